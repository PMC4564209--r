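#' 3-D scalar volume
#'
#' A `volume` is the package's basic container: a 3-D array of finite scalars
#' together with its voxel spacing (mm) and world origin (mm). Voxel centers
#' live at `index * spacing + origin` with 0-based indices, and all
#' interpolation and transforms operate in that world frame, so voxel
#' anisotropy never leaks into transform parameters.
#'
#' @param data 3-D numeric array; all values must be finite.
#' @param spacing numeric length-3, voxel side lengths in mm (all > 0).
#' @param origin numeric length-3, world coordinates (mm) of voxel (0,0,0).
#' @return An object of class `volume` with elements `data`, `spacing`,
#'   `origin`.
#' @export
as_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (inherits(data, "volume")) return(data)
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop("volume data must be a 3-D array, got ", length(dim(data)), " dimensions")
  if (any(dim(data) < 1L)) stop("all three dimensions must be >= 1")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive finite lengths (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be 3 finite world coordinates (mm)")
  n_bad <- sum(!is.finite(data))
  if (n_bad > 0L)
    stop("volume contains ", n_bad, " non-finite voxel(s)")
  storage.mode(data) <- "double"
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "volume")
}

#' @export
print.volume <- function(x, ...) {
  cat(sprintf("<volume> %s voxels, spacing (%s) mm, origin (%s) mm\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = ", "),
              paste(signif(x$origin, 4), collapse = ", ")))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.volume <- function(x) dim(x$data)

#' Number of voxels in a volume
#'
#' @param volume a `volume` or `label_volume`.
#' @return Integer-valued scalar, the product of the three dimensions.
#' @export
n_voxels <- function(volume) prod(dim(volume$data))

#' Integer label volume
#'
#' Like [as_volume()] but for non-negative integer structure labels, with 0
#' reserved for background. Used for overlap-based registration assessment.
#'
#' @inheritParams as_volume
#' @return An object of class `label_volume` (also a `volume`).
#' @export
as_label_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (inherits(data, "label_volume")) return(data)
  if (inherits(data, "volume")) {
    spacing <- data$spacing
    origin <- data$origin
    data <- data$data
  }
  v <- as_volume(data, spacing, origin)
  if (any(v$data < 0) || any(v$data != round(v$data)))
    stop("labels must be non-negative integers (0 = background)")
  class(v) <- c("label_volume", "volume")
  v
}

#' Read a 3-D NIfTI-1 volume
#'
#' Loads a single 3-D scalar image (.nii or .nii.gz). Spacing is taken from
#' the header's pixdim and the origin from the translation column of the
#' stored xform; orientation beyond spacing/origin is not used in
#' computation. Data are cast to double.
#'
#' @param path path to a NIfTI-1 file.
#' @param labels if `TRUE` return a [as_label_volume()] (integer labels).
#' @return A `volume` (or `label_volume`).
#' @export
read_volume <- function(path, labels = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img2 <- array(as.vector(img), dim = d[1:3])
  } else if (length(d) == 3L) {
    img2 <- array(as.vector(img), dim = d)
  } else {
    stop("expected a single 3-D scalar image, got dimensions ",
         paste(d, collapse = "x"))
  }
  n_bad <- sum(!is.finite(img2))
  if (n_bad > 0L)
    stop("image has ", n_bad, " non-finite voxel(s): refusing to load")
  spacing <- abs(RNifti::pixdim(img)[1:3])
  xf <- tryCatch(unclass(RNifti::xform(img)), error = function(e) NULL)
  origin <- if (is.null(xf)) c(0, 0, 0) else as.numeric(xf[1:3, 4])
  if (labels) as_label_volume(img2, spacing, origin)
  else as_volume(img2, spacing, origin)
}

#' Write a volume as NIfTI-1
#'
#' The file round-trips through [read_volume()] with identical dimensions,
#' spacing and origin. Label volumes are stored as integers.
#'
#' @param volume a `volume` or `label_volume`.
#' @param path output path ending in .nii or .nii.gz; parent must exist.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  volume <- if (inherits(volume, "label_volume")) volume else as_volume(volume)
  if (!dir.exists(dirname(path))) stop("parent directory does not exist: ", dirname(path))
  dat <- volume$data
  if (inherits(volume, "label_volume")) storage.mode(dat) <- "integer"
  img <- RNifti::asNifti(dat)
  RNifti::pixdim(img) <- volume$spacing
  m <- diag(c(volume$spacing, 1))
  m[1:3, 4] <- volume$origin
  RNifti::qform(img) <- structure(m, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

# world coordinates (mm) of all voxel centers, as an N x 3 matrix in
# column-major (linear index) order
voxel_centers <- function(volume) {
  d <- dim(volume$data)
  i <- (seq_len(d[1]) - 1) * volume$spacing[1] + volume$origin[1]
  j <- (seq_len(d[2]) - 1) * volume$spacing[2] + volume$origin[2]
  k <- (seq_len(d[3]) - 1) * volume$spacing[3] + volume$origin[3]
  cbind(rep(i, times = d[2] * d[3]),
        rep(rep(j, each = d[1]), times = d[3]),
        rep(k, each = d[1] * d[2]))
}

# physical center of the volume (mm), midway across the voxel-center span
volume_center <- function(volume) {
  volume$origin + (dim(volume$data) - 1) / 2 * volume$spacing
}
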