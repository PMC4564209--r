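# run code under a fixed RNG seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic brain-like phantom
#'
#' The phantom emulates a T1-like head: nested smooth ellipsoidal structures
#' (an outer scalp/skull shell, a cortex-like annulus and a dark
#' ventricle-like core, slightly off-centre so the shape has no rotational
#' symmetry) with distinct piecewise-constant mean intensities on a zero
#' background, additive Gaussian noise, and an optional smooth multiplicative
#' intensity bias.
#'
#' @param size voxels per axis (scalar or length 3, each >= 16).
#' @param means per-structure mean intensities, outermost first; their
#'   number sets the number of nested structures. Default `c(60, 110, 25)`,
#'   dim core inside a bright cortex inside a mid-intensity shell.
#' @param noise_sd additive noise standard deviation; the default 2.2 is 2
#'   percent of the peak intensity contrast (110 against the 0 background).
#' @param bias_amplitude relative amplitude of the multiplicative bias field
#'   (0 disables it).
#' @param bias_sigma_mm smoothness (Gaussian width, mm) of the bias field.
#' @param spacing voxel spacing in mm.
#' @param seed RNG seed; the same seed reproduces the phantom bit for bit.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(size = 64, means = c(60, 110, 25), noise_sd = 2.2,
                         bias_amplitude = 0, bias_sigma_mm = 20,
                         spacing = c(1, 1, 1), seed = 0) {
  size <- rep(as.integer(size), length.out = 3)
  if (any(size < 16)) stop("phantom size must be >= 16 per axis")
  if (anyDuplicated(means)) stop("structure mean intensities must be distinct")
  if (length(means) < 1 || length(means) > 5)
    stop("between 1 and 5 nested structures are supported")
  if (noise_sd < 0 || bias_amplitude < 0) stop("noise and bias must be >= 0")
  structure(list(size = size, means = as.numeric(means), noise_sd = noise_sd,
                 bias_amplitude = bias_amplitude, bias_sigma_mm = bias_sigma_mm,
                 spacing = as.numeric(spacing), seed = seed),
            class = "phantom_spec")
}

# semi-axes (voxel units per axis) of the k-th nested ellipsoid
phantom_semi_axes <- function(size, k, n) {
  fracs <- seq(0.88, 0.22, length.out = max(n, 2))
  aniso <- c(1, 0.86, 0.94)  # distinct per-axis extents: no spherical symmetry
  fracs[k] * aniso * (size - 1) / 2
}

#' Generate a synthetic phantom volume with labels
#'
#' @param spec a [phantom_spec()].
#' @return List with `volume` (the intensity `volume`) and `labels` (a
#'   `label_volume`, structure k labelled k, outermost first, background 0).
#' @export
make_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$size
  n <- length(spec$means)
  ctr <- (d - 1) / 2
  x <- (seq_len(d[1]) - 1) - ctr[1]
  y <- (seq_len(d[2]) - 1) - ctr[2]
  z <- (seq_len(d[3]) - 1) - ctr[3]
  gx <- array(rep(x, times = d[2] * d[3]), d)
  gy <- array(rep(rep(y, each = d[1]), times = d[3]), d)
  gz <- array(rep(z, each = d[1] * d[2]), d)
  vol <- array(0, d)
  lab <- array(0L, d)
  for (k in seq_len(n)) {
    ax <- phantom_semi_axes(d, k, n)
    # innermost structure sits off-centre to break point symmetry
    off <- if (k == n && n > 1) c(0.10, 0.06, -0.04) * (d - 1) / 2 else c(0, 0, 0)
    inside <- ((gx - off[1]) / ax[1])^2 + ((gy - off[2]) / ax[2])^2 +
      ((gz - off[3]) / ax[3])^2 <= 1
    vol[inside] <- spec$means[k]
    lab[inside] <- k
  }
  vol_clean <- vol
  if (spec$noise_sd > 0 || spec$bias_amplitude > 0) {
    vol <- with_seed(spec$seed, {
      v <- vol_clean
      if (spec$bias_amplitude > 0) {
        b <- array(stats::rnorm(prod(d)), d)
        b <- smooth_gaussian(b, spec$bias_sigma_mm, spec$spacing)
        b <- b / max(abs(b))
        v <- v * (1 + spec$bias_amplitude * b)
      }
      if (spec$noise_sd > 0)
        v <- v + stats::rnorm(prod(d), sd = spec$noise_sd)
      v
    })
  }
  list(volume = as_volume(vol, spec$spacing),
       labels = as_label_volume(lab, spec$spacing))
}

#' Move a phantom through a known affine transform
#'
#' Builds the ground-truth transform T from the 12 parameters (about the
#' volume's physical center) and resamples the volume through the inverse
#' map, so that registering the moved volume back to the original should
#' recover exactly these parameters. Labels are carried nearest-neighbour.
#'
#' @param volume the phantom `volume`.
#' @param labels its `label_volume` (or `NULL`).
#' @param params 12 affine parameters as in [affine_from_params()].
#' @param min_overlap smallest acceptable fraction of moved voxels that map
#'   inside the original extent (default 0.6).
#' @return List with `volume`, `labels` and `transform` (the ground truth
#'   `affine_transform`, reference -> moving).
#' @export
apply_known_affine <- function(volume, labels = NULL, params,
                               min_overlap = 0.6) {
  volume <- as_volume(volume)
  tr <- affine_from_params(params, center = volume_center(volume))
  inv <- affine_inverse(tr)
  st <- sample_transformed(volume, inv, volume)
  frac <- mean(st$overlap)
  if (frac < min_overlap)
    stop(sprintf("transform keeps only %.0f%% overlap (need >= %.0f%%)",
                 100 * frac, 100 * min_overlap))
  moved <- as_volume(st$values, volume$spacing, volume$origin)
  moved_labels <- NULL
  if (!is.null(labels))
    moved_labels <- transform_labels(as_label_volume(labels), inv, volume)
  list(volume = moved, labels = moved_labels, transform = tr)
}

#' Deform a phantom by a known smooth random field
#'
#' Builds a smooth displacement field by Gaussian-filtering white noise and
#' rescaling each component to the requested amplitude, then warps the
#' volume (and labels, nearest-neighbour) through it. The field is returned
#' so registration error can be measured against it.
#'
#' @param volume the phantom `volume`.
#' @param labels its `label_volume` (or `NULL`).
#' @param amplitude_mm per-axis maximum displacement (mm).
#' @param sigma_mm smoothness (Gaussian width, mm); must be at least twice
#'   the amplitude to keep the warp invertible in practice.
#' @param seed RNG seed.
#' @return List with `volume`, `labels` and `field` (the ground-truth
#'   `displacement_field`).
#' @export
apply_known_deformation <- function(volume, labels = NULL, amplitude_mm,
                                    sigma_mm, seed = 0) {
  volume <- as_volume(volume)
  if (amplitude_mm < 0 || sigma_mm <= 0)
    stop("amplitude and smoothness must be non-negative / positive")
  if (amplitude_mm > sigma_mm / 2)
    stop("amplitude must not exceed half the smoothness (invertibility)")
  d <- dim(volume$data)
  u <- array(0, c(d, 3))
  if (amplitude_mm > 0) {
    u <- with_seed(seed, {
      uu <- array(stats::rnorm(prod(d) * 3), c(d, 3))
      for (c3 in 1:3) {
        s <- smooth_gaussian(uu[, , , c3], sigma_mm, volume$spacing,
                             boundary = "zero")
        uu[, , , c3] <- s / max(abs(s)) * amplitude_mm
      }
      uu
    })
  }
  field <- displacement_field(u, volume$spacing, volume$origin)
  moved <- warp(volume, field)
  moved_labels <- NULL
  if (!is.null(labels)) {
    labels <- as_label_volume(labels)
    moved_labels <- transform_labels(labels, field, volume)
  }
  list(volume = moved, labels = moved_labels, field = field)
}
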