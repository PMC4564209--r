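#' Affine transform in world (mm) coordinates
#'
#' A 4x4 homogeneous matrix mapping world points of the reference frame into
#' the moving image's world frame. The parameterization used by the search is
#' 3 translations (mm), 3 rotations (radians, applied as Rx %*% Ry %*% Rz),
#' 3 scales and 3 shears, all about a configurable rotation center.
#'
#' @param matrix 4x4 numeric matrix with last row (0, 0, 0, 1).
#' @return An object of class `affine_transform`.
#' @export
affine_transform <- function(matrix = diag(4)) {
  matrix <- as.matrix(matrix)
  if (!all(dim(matrix) == c(4, 4)) || any(!is.finite(matrix)))
    stop("affine matrix must be a finite 4x4 matrix")
  if (max(abs(matrix[4, ] - c(0, 0, 0, 1))) > 1e-9)
    stop("last row of an affine matrix must be (0, 0, 0, 1)")
  if (abs(det(matrix[1:3, 1:3])) < 1e-12)
    stop("affine matrix is singular")
  structure(list(matrix = matrix), class = "affine_transform")
}

#' @export
print.affine_transform <- function(x, ...) {
  cat("<affine_transform>\n")
  print(unname(x$matrix))
  invisible(x)
}

#' Identity transform
#' @return The identity `affine_transform`.
#' @export
affine_identity <- function() affine_transform(diag(4))

#' Compose two affine transforms
#'
#' `compose(a, b)` maps a point p to `a(b(p))`.
#'
#' @param a,b `affine_transform` objects.
#' @return The composed `affine_transform`.
#' @export
compose <- function(a, b) affine_transform(a$matrix %*% b$matrix)

#' Invert an affine transform
#' @param transform an `affine_transform`.
#' @return The inverse `affine_transform`.
#' @export
affine_inverse <- function(transform) affine_transform(solve(transform$matrix))

rot_x <- function(a) rbind(c(1, 0, 0), c(0, cos(a), -sin(a)), c(0, sin(a), cos(a)))
rot_y <- function(a) rbind(c(cos(a), 0, sin(a)), c(0, 1, 0), c(-sin(a), 0, cos(a)))
rot_z <- function(a) rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0), c(0, 0, 1))

#' Build an affine transform from 12 parameters
#'
#' Parameters in order: translations tx, ty, tz (mm); rotations rx, ry, rz
#' (radians, composed as Rx %*% Ry %*% Rz); scales sx, sy, sz; shears hxy,
#' hxz, hyz (unit upper-triangular). The linear part is
#' `R %*% diag(s) %*% H`, applied about `center`, then translated.
#'
#' @param params numeric vector of length 12 (trailing entries may be
#'   omitted: defaults are zero translations/rotations/shears, unit scales).
#' @param center length-3 rotation/scaling center in world mm (default
#'   origin).
#' @return An `affine_transform`.
#' @export
affine_from_params <- function(params, center = c(0, 0, 0)) {
  p <- c(0, 0, 0, 0, 0, 0, 1, 1, 1, 0, 0, 0)
  params <- as.numeric(params)
  if (length(params) > 12L) stop("at most 12 affine parameters")
  p[seq_along(params)] <- params
  rot <- rot_x(p[4]) %*% rot_y(p[5]) %*% rot_z(p[6])
  shear <- rbind(c(1, p[10], p[11]), c(0, 1, p[12]), c(0, 0, 1))
  a <- rot %*% diag(p[7:9]) %*% shear
  m <- diag(4)
  m[1:3, 1:3] <- a
  m[1:3, 4] <- p[1:3] + center - a %*% center
  affine_transform(m)
}

#' Recover the 12 parameters of an affine transform
#'
#' Inverse of [affine_from_params()]: decomposes the linear part as
#' rotation x scale x shear via a sign-fixed QR factorization and extracts
#' Euler angles for the Rx %*% Ry %*% Rz convention. Round-trips to 1e-9 for
#' positive scales and rotations in the principal range.
#'
#' @param transform an `affine_transform`.
#' @param center the same center used to build the transform.
#' @return Named numeric vector of length 12.
#' @export
params_from_affine <- function(transform, center = c(0, 0, 0)) {
  a <- transform$matrix[1:3, 1:3]
  qrd <- qr(a)
  q <- qr.Q(qrd); r <- qr.R(qrd)
  sgn <- sign(diag(r)); sgn[sgn == 0] <- 1
  q <- q %*% diag(sgn); r <- diag(sgn) %*% r
  if (det(q) < 0) { q <- -q; r <- -r }  # keep a proper rotation
  s <- diag(r)
  shear <- c(hxy = r[1, 2] / s[1], hxz = r[1, 3] / s[1], hyz = r[2, 3] / s[2])
  ry <- asin(max(-1, min(1, q[1, 3])))
  rx <- atan2(-q[2, 3], q[3, 3])
  rz <- atan2(-q[1, 2], q[1, 1])
  trans <- transform$matrix[1:3, 4] - center + a %*% center
  out <- c(trans, rx, ry, rz, s, shear)
  names(out) <- c("tx", "ty", "tz", "rx", "ry", "rz",
                  "sx", "sy", "sz", "hxy", "hxz", "hyz")
  out
}

#' Write an affine transform as a 4x4 text file
#'
#' FSL-style layout: four lines of four whitespace-separated numbers.
#'
#' @param transform an `affine_transform`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_affine <- function(transform, path) {
  m <- transform$matrix
  lines <- apply(m, 1, function(r) paste(sprintf("%.12g", r), collapse = "  "))
  writeLines(lines, path)
  invisible(path)
}

#' Read a 4x4 affine transform text file
#' @param path path to a file of 4 lines x 4 numbers.
#' @return An `affine_transform`.
#' @export
read_affine <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  m <- as.matrix(utils::read.table(path))
  if (!all(dim(m) == c(4, 4))) stop("expected 4 lines of 4 numbers in ", path)
  affine_transform(unname(m))
}

# apply the transform to an N x 3 matrix of world points
transform_points <- function(transform, pts) {
  pts %*% t(transform$matrix[1:3, 1:3]) +
    matrix(transform$matrix[1:3, 4], nrow(pts), 3, byrow = TRUE)
}
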