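#' Displacement field on a volume grid
#'
#' Per-voxel 3-vector displacements u(x) in mm: a warped image samples its
#' source at x + u(x). The zero field is the identity warp.
#'
#' @param vectors 4-D array `dims x 3` of displacements in mm (or `NULL` for
#'   a zero field of dimensions `dims`).
#' @param spacing,origin grid geometry, as in [as_volume()].
#' @param dims grid dimensions when `vectors` is `NULL`.
#' @return An object of class `displacement_field`.
#' @export
displacement_field <- function(vectors = NULL, spacing = c(1, 1, 1),
                               origin = c(0, 0, 0), dims = NULL) {
  if (is.null(vectors)) {
    if (is.null(dims)) stop("need either vectors or dims")
    vectors <- array(0, c(dims, 3))
  }
  vectors <- as.array(vectors)
  if (length(dim(vectors)) != 4L || dim(vectors)[4] != 3L)
    stop("displacement vectors must be a dims x 3 array")
  if (any(!is.finite(vectors))) stop("displacement field has non-finite values")
  structure(list(u = vectors, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "displacement_field")
}

# zero field matching a volume's grid
zero_field <- function(volume) {
  displacement_field(dims = dim(volume$data), spacing = volume$spacing,
                     origin = volume$origin)
}

#' Warp a volume through a displacement field
#'
#' Output voxel at position x takes the trilinearly interpolated source value
#' at x + u(x); samples outside the source extent clamp to the nearest edge
#' value.
#'
#' @param volume a `volume`.
#' @param field a `displacement_field` on the same grid.
#' @return The warped `volume`.
#' @export
warp <- function(volume, field) {
  volume <- as_volume(volume)
  d <- dim(volume$data)
  if (!identical(dim(field$u)[1:3], d))
    stop("field grid does not match the volume")
  idx <- base_index_grids(d)
  x <- idx$i + field$u[, , , 1] / volume$spacing[1]
  y <- idx$j + field$u[, , , 2] / volume$spacing[2]
  z <- idx$k + field$u[, , , 3] / volume$spacing[3]
  vals <- interp_trilinear(volume$data, as.vector(x), as.vector(y), as.vector(z))
  as_volume(array(vals, d), volume$spacing, volume$origin)
}

# 0-based index grids for a dim vector
base_index_grids <- function(d) {
  list(i = array(rep(0:(d[1] - 1), times = d[2] * d[3]), d),
       j = array(rep(rep(0:(d[2] - 1), each = d[1]), times = d[3]), d),
       k = array(rep(0:(d[3] - 1), each = d[1] * d[2]), d))
}

# separable Gaussian smoothing; sigma in mm per axis. boundary "replicate"
# clamps to the edge value (used on images and fields); "zero" treats outside
# as 0, so smoothed noise tapers toward the boundary instead of having its
# variance inflated there (used when synthesizing random deformations).
smooth_gaussian <- function(arr, sigma_mm, spacing, boundary = "replicate") {
  d <- dim(arr)
  for (axis in 1:3) {
    sig <- sigma_mm / spacing[axis]
    if (sig < 1e-6) next
    half <- max(1L, as.integer(ceiling(3 * sig)))
    taps <- (-half):half
    w <- exp(-0.5 * (taps / sig)^2)
    w <- w / sum(w)
    perm <- c(axis, setdiff(1:3, axis))
    m <- matrix(aperm(arr, perm), nrow = d[axis])
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    for (t in seq_along(taps)) {
      pos <- seq_len(n) + taps[t]
      if (boundary == "replicate") {
        src <- pmin.int(pmax.int(pos, 1L), n)
        out <- out + w[t] * m[src, , drop = FALSE]
      } else {
        ok <- pos >= 1L & pos <= n
        if (any(ok))
          out[ok, ] <- out[ok, ] + w[t] * m[pos[ok], , drop = FALSE]
      }
    }
    arr <- aperm(array(out, dim = d[perm]), order(perm))
  }
  arr
}

smooth_field <- function(field, sigma_mm) {
  if (sigma_mm < 1e-6) return(field)
  u <- field$u
  for (c3 in 1:3)
    u[, , , c3] <- smooth_gaussian(u[, , , c3], sigma_mm, field$spacing)
  displacement_field(u, field$spacing, field$origin)
}

# central-difference gradient, per mm, edge replicated
gradient_mm <- function(arr, spacing) {
  d <- dim(arr)
  g <- array(0, c(d, 3))
  for (axis in 1:3) {
    n <- d[axis]
    hi <- pmin.int(seq_len(n) + 1L, n)
    lo <- pmax.int(seq_len(n) - 1L, 1L)
    denom <- (hi - lo) * spacing[axis]
    denom[denom == 0] <- 1
    if (axis == 1) {
      g[, , , 1] <- (arr[hi, , , drop = FALSE] - arr[lo, , , drop = FALSE]) /
        array(denom, d)
    } else if (axis == 2) {
      g[, , , 2] <- (arr[, hi, , drop = FALSE] - arr[, lo, , drop = FALSE]) /
        array(rep(denom, each = d[1]), d)
    } else {
      g[, , , 3] <- (arr[, , hi, drop = FALSE] - arr[, , lo, drop = FALSE]) /
        array(rep(denom, each = d[1] * d[2]), d)
    }
  }
  g
}

#' Configuration for the symmetric deformable refinement
#'
#' @param radius local correlation window radius r, voxels (default 3 for
#'   the modest volume sizes this greedy scheme targets; the metric itself
#'   supports up to 8).
#' @param iterations iterations per pyramid level.
#' @param step_voxels update step length as a fraction of a voxel (each half
#'   field receives half of it).
#' @param update_sigma_mm,field_sigma_mm Gaussian smoothing of the update
#'   and of the accumulated fields, mm.
#' @param levels downsampling factors of the internal pyramid, coarse to
#'   fine (default `c(2, 1)`).
#' @param tol minimum mean-CC improvement to accept a step.
#' @param seed seed (the scheme is deterministic; kept for interface parity).
#' @return A `sym_config` list.
#' @export
sym_config <- function(radius = 3, iterations = 30, step_voxels = 0.5,
                       update_sigma_mm = 3, field_sigma_mm = 1.5,
                       levels = c(2, 1), tol = 1e-7, seed = 0) {
  if (radius < 1 || radius > 8) stop("radius must be between 1 and 8")
  if (step_voxels <= 0 || update_sigma_mm <= 0 || field_sigma_mm <= 0)
    stop("steps and smoothing widths must be positive")
  structure(list(radius = as.integer(radius), iterations = as.integer(iterations),
                 step_voxels = step_voxels, update_sigma_mm = update_sigma_mm,
                 field_sigma_mm = field_sigma_mm, levels = as.integer(levels),
                 tol = tol, seed = seed),
            class = "sym_config")
}

#' One symmetric update step
#'
#' Warps both images halfway through their current fields, evaluates the
#' local CC map, and moves each field a half-step along a direction that
#' locally increases CC (the per-voxel derivative of C^2/(AB) with respect
#' to each image's value, carried through the image gradient), smoothing the
#' update and the fields with the configured Gaussian widths. If the mean
#' local CC does not increase the step is rejected and the input fields are
#' returned unchanged.
#'
#' @param fixed,moving co-dimensioned `volume`s.
#' @param phi1,phi2 current half-way `displacement_field`s for the fixed and
#'   moving image.
#' @param config a [sym_config()].
#' @param step_voxels optional override of the step length.
#' @return List with `phi1`, `phi2`, `mean_cc` (attained value) and
#'   `accepted`.
#' @export
symmetric_step <- function(fixed, moving, phi1, phi2, config = sym_config(),
                           step_voxels = config$step_voxels) {
  fixed <- as_volume(fixed); moving <- as_volume(moving)
  if (!identical(dim(fixed$data), dim(moving$data)))
    stop("fixed and moving must be co-dimensioned")
  it <- warp(fixed, phi1)
  jt <- warp(moving, phi2)
  inter <- cc_intermediates(window_sums(it, jt, config$radius))
  ccm <- cc_map(inter)
  cc0 <- mean_cc(ccm)
  if (step_voxels <= 0)
    return(list(phi1 = phi1, phi2 = phi2, mean_cc = cc0, accepted = FALSE))
  ab <- inter$a * inter$b
  valid <- ccm$valid
  coef <- array(0, dim(ab))
  coef[valid] <- 2 * inter$c[valid] / ab[valid]
  di <- it$data - inter$mean_i
  dj <- jt$data - inter$mean_j
  rba <- array(0, dim(ab)); rba[valid] <- inter$c[valid] / inter$b[valid]
  rab <- array(0, dim(ab)); rab[valid] <- inter$c[valid] / inter$a[valid]
  gj_coef <- coef * (di - rba * dj)   # d cc / d J_T
  gi_coef <- coef * (dj - rab * di)   # d cc / d I_T
  g_it <- gradient_mm(it$data, fixed$spacing)
  g_jt <- gradient_mm(jt$data, moving$spacing)
  d1 <- g_it * array(gi_coef, dim(g_it))
  d2 <- g_jt * array(gj_coef, dim(g_jt))
  # smooth the raw update first, then normalize its largest displacement to
  # half the step (each half-way field takes half of the full step)
  for (c3 in 1:3) {
    d1[, , , c3] <- smooth_gaussian(d1[, , , c3], config$update_sigma_mm,
                                    fixed$spacing)
    d2[, , , c3] <- smooth_gaussian(d2[, , , c3], config$update_sigma_mm,
                                    moving$spacing)
  }
  mag <- max(sqrt(rowSums(matrix(d1, ncol = 3)^2)),
             sqrt(rowSums(matrix(d2, ncol = 3)^2)))
  if (!is.finite(mag) || mag <= 0)
    return(list(phi1 = phi1, phi2 = phi2, mean_cc = cc0, accepted = FALSE))
  step_mm <- step_voxels * min(fixed$spacing)
  scale <- (step_mm / 2) / mag
  d1 <- d1 * scale; d2 <- d2 * scale
  p1 <- smooth_field(displacement_field(phi1$u + d1, phi1$spacing, phi1$origin),
                     config$field_sigma_mm)
  p2 <- smooth_field(displacement_field(phi2$u + d2, phi2$spacing, phi2$origin),
                     config$field_sigma_mm)
  it2 <- warp(fixed, p1)
  jt2 <- warp(moving, p2)
  cc1 <- mean_cc(cc_map(cc_intermediates(window_sums(it2, jt2, config$radius))))
  if (cc1 > cc0 + config$tol)
    list(phi1 = p1, phi2 = p2, mean_cc = cc1, accepted = TRUE)
  else
    list(phi1 = phi1, phi2 = phi2, mean_cc = cc0, accepted = FALSE)
}

# invert a displacement field by fixed-point iteration
invert_field <- function(field, max_iter = 20, tol_voxels = 1e-3) {
  d <- dim(field$u)[1:3]
  sp <- field$spacing
  idx <- base_index_grids(d)
  v <- array(0, dim(field$u))
  for (it in seq_len(max_iter)) {
    x <- as.vector(idx$i + v[, , , 1] / sp[1])
    y <- as.vector(idx$j + v[, , , 2] / sp[2])
    z <- as.vector(idx$k + v[, , , 3] / sp[3])
    vn <- v
    for (c3 in 1:3)
      vn[, , , c3] <- -array(interp_trilinear(field$u[, , , c3], x, y, z), d)
    delta <- max(abs(vn - v)) / min(sp)
    v <- vn
    if (delta < tol_voxels) break
  }
  displacement_field(v, field$spacing, field$origin)
}

# interpolate a field's vectors at positions x + v(x) and compose:
# u_out(x) = v(x) + u(x + v(x))
compose_fields <- function(v, u) {
  d <- dim(v$u)[1:3]
  sp <- v$spacing
  idx <- base_index_grids(d)
  x <- as.vector(idx$i + v$u[, , , 1] / sp[1])
  y <- as.vector(idx$j + v$u[, , , 2] / sp[2])
  z <- as.vector(idx$k + v$u[, , , 3] / sp[3])
  out <- v$u
  for (c3 in 1:3)
    out[, , , c3] <- out[, , , c3] +
      array(interp_trilinear(u$u[, , , c3], x, y, z), d)
  displacement_field(out, v$spacing, v$origin)
}

# resample a field's vectors onto a finer grid (values are mm, unchanged)
upsample_field <- function(field, target) {
  d <- dim(target$data)
  cx <- ((seq_len(d[1]) - 1) * target$spacing[1] + target$origin[1] -
           field$origin[1]) / field$spacing[1]
  cy <- ((seq_len(d[2]) - 1) * target$spacing[2] + target$origin[2] -
           field$origin[2]) / field$spacing[2]
  cz <- ((seq_len(d[3]) - 1) * target$spacing[3] + target$origin[3] -
           field$origin[3]) / field$spacing[3]
  x <- rep(cx, times = d[2] * d[3])
  y <- rep(rep(cy, each = d[1]), times = d[3])
  z <- rep(cz, each = d[1] * d[2])
  u <- array(0, c(d, 3))
  for (c3 in 1:3)
    u[, , , c3] <- array(interp_trilinear(field$u[, , , c3], x, y, z), d)
  displacement_field(u, target$spacing, target$origin)
}

#' Symmetric deformable registration by greedy CC ascent
#'
#' A simplified symmetric scheme: two half-way displacement fields phi1 and
#' phi2 warp the reference and the moving image toward a common midpoint and
#' are updated greedily, coarse to fine, so that the mean local squared
#' cross-correlation never decreases over accepted steps. The step length is
#' halved whenever an update is rejected. The final warp of the moving image
#' onto the reference grid composes the inverse of phi1 with phi2.
#'
#' @param reference reference `volume`.
#' @param moving moving `volume` (same grid, or supply `init`).
#' @param init optional `affine_transform` applied to the moving image first.
#' @param config a [sym_config()].
#' @return List with `phi1`, `phi2`, `field` (composed reference-to-moving
#'   displacement), `warped` (moving resampled onto the reference grid),
#'   `trace` (per-level vectors of accepted mean-CC values, each
#'   non-decreasing) and `mean_cc`.
#' @export
register_symmetric <- function(reference, moving, init = NULL,
                               config = sym_config()) {
  reference <- as_volume(reference)
  moving <- as_volume(moving)
  if (!is.null(init))
    moving <- resample_affine(moving, init, reference)
  if (!identical(dim(reference$data), dim(moving$data)))
    stop("reference and moving must share a grid (use init for affine pre-alignment)")
  levels <- sort(unique(config$levels), decreasing = TRUE)
  vols <- list()
  for (f in levels) {
    rf <- reference; mv <- moving
    times <- as.integer(round(log2(f)))
    for (t in seq_len(times)) { rf <- block_downsample(rf); mv <- block_downsample(mv) }
    vols[[as.character(f)]] <- list(ref = rf, mov = mv)
  }
  phi1 <- phi2 <- NULL
  trace <- list()
  for (f in levels) {
    rf <- vols[[as.character(f)]]$ref
    mv <- vols[[as.character(f)]]$mov
    if (is.null(phi1)) {
      phi1 <- zero_field(rf); phi2 <- zero_field(rf)
    } else {
      phi1 <- upsample_field(phi1, rf); phi2 <- upsample_field(phi2, rf)
    }
    step <- config$step_voxels
    it0 <- warp(rf, phi1); jt0 <- warp(mv, phi2)
    cc_cur <- mean_cc(cc_map(cc_intermediates(window_sums(it0, jt0, config$radius))))
    level_trace <- cc_cur
    for (iter in seq_len(config$iterations)) {
      res <- symmetric_step(rf, mv, phi1, phi2, config, step_voxels = step)
      if (res$accepted) {
        phi1 <- res$phi1; phi2 <- res$phi2
        cc_cur <- res$mean_cc
        level_trace <- c(level_trace, cc_cur)
      } else {
        step <- step / 2
        if (step < 0.02) break
      }
    }
    # mean CC is only comparable within a level (the grid changes between
    # levels), so the accepted trace is reported per level
    trace[[paste0("level_", f)]] <- level_trace
  }
  vfield <- invert_field(phi1)
  total <- compose_fields(vfield, phi2)
  warped <- warp(moving, total)
  list(phi1 = phi1, phi2 = phi2, field = total, warped = warped,
       trace = trace, mean_cc = cc_cur)
}

#' Write a displacement field as NIfTI
#'
#' Stored as a 4-D image with a trailing 3-component dimension (mm units).
#'
#' @param field a `displacement_field`.
#' @param path output .nii/.nii.gz path.
#' @return `path`, invisibly.
#' @export
write_field <- function(field, path) {
  img <- RNifti::asNifti(field$u)
  RNifti::pixdim(img) <- c(field$spacing, 1)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a displacement field written by [write_field()]
#' @param path input path.
#' @param origin world origin of the field grid (not stored; default 0).
#' @return A `displacement_field`.
#' @export
read_field <- function(path, origin = c(0, 0, 0)) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L || d[4] != 3L)
    stop("expected a 4-D field with trailing dimension 3")
  displacement_field(array(as.vector(img), d), abs(RNifti::pixdim(img)[1:3]),
                     origin)
}
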