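# Trilinear interpolation at continuous 0-based voxel coordinates.
# Coordinates are clamped to [0, dim-1] per axis, i.e. samples outside the
# grid take the nearest edge value.
interp_trilinear <- function(arr, x, y, z) {
  d <- dim(arr)
  x <- pmin.int(pmax.int(x, 0), d[1] - 1)
  y <- pmin.int(pmax.int(y, 0), d[2] - 1)
  z <- pmin.int(pmax.int(z, 0), d[3] - 1)
  i0 <- floor(x); j0 <- floor(y); k0 <- floor(z)
  fx <- x - i0; fy <- y - j0; fz <- z - k0
  i1 <- pmin.int(i0 + 1, d[1] - 1)
  j1 <- pmin.int(j0 + 1, d[2] - 1)
  k1 <- pmin.int(k0 + 1, d[3] - 1)
  sxy <- d[1] * d[2]
  b00 <- k0 * sxy; b01 <- k1 * sxy
  a0 <- j0 * d[1]; a1 <- j1 * d[1]
  v000 <- arr[b00 + a0 + i0 + 1]; v100 <- arr[b00 + a0 + i1 + 1]
  v010 <- arr[b00 + a1 + i0 + 1]; v110 <- arr[b00 + a1 + i1 + 1]
  v001 <- arr[b01 + a0 + i0 + 1]; v101 <- arr[b01 + a0 + i1 + 1]
  v011 <- arr[b01 + a1 + i0 + 1]; v111 <- arr[b01 + a1 + i1 + 1]
  w00 <- v000 + (v100 - v000) * fx
  w10 <- v010 + (v110 - v010) * fx
  w01 <- v001 + (v101 - v001) * fx
  w11 <- v011 + (v111 - v011) * fx
  u0 <- w00 + (w10 - w00) * fy
  u1 <- w01 + (w11 - w01) * fy
  u0 + (u1 - u0) * fz
}

# Nearest-neighbour sampling at continuous 0-based voxel coordinates; out-of
# -grid coordinates return `outside`.
interp_nearest <- function(arr, x, y, z, outside = 0) {
  d <- dim(arr)
  inside <- x >= -0.5 & x <= d[1] - 0.5 &
            y >= -0.5 & y <= d[2] - 0.5 &
            z >= -0.5 & z <= d[3] - 0.5
  i <- pmin.int(pmax.int(round(x), 0), d[1] - 1)
  j <- pmin.int(pmax.int(round(y), 0), d[2] - 1)
  k <- pmin.int(pmax.int(round(z), 0), d[3] - 1)
  out <- arr[k * d[1] * d[2] + j * d[1] + i + 1]
  out[!inside] <- outside
  out
}

#' Resample a volume to an isotropic grid
#'
#' Produces a volume with cubic voxels of side `target_mm`. Output dimensions
#' are `ceiling(extent / target_mm)` where the extent is `dim * spacing`;
#' values are trilinearly interpolated at the new voxel centers, and samples
#' falling outside the source voxel-center span take the nearest edge value.
#' The origin is preserved, so the first voxel center does not move.
#'
#' @param volume a `volume`.
#' @param target_mm positive isotropic voxel size in mm (default 1, the
#'   finest level of the registration pyramid).
#' @return A `volume` with spacing `c(target_mm, target_mm, target_mm)`.
#' @export
resample_isotropic <- function(volume, target_mm = 1) {
  volume <- as_volume(volume)
  if (!is.numeric(target_mm) || length(target_mm) != 1L || target_mm <= 0)
    stop("target_mm must be a positive scalar")
  d <- dim(volume$data)
  if (any(d < 2L))
    stop("cannot resample a degenerate (single-slice) axis; dims: ",
         paste(d, collapse = "x"))
  extent <- d * volume$spacing
  nd <- pmax(as.integer(ceiling(extent / target_mm)), 1L)
  # continuous source indices of the new voxel centers
  gx <- (seq_len(nd[1]) - 1) * target_mm / volume$spacing[1]
  gy <- (seq_len(nd[2]) - 1) * target_mm / volume$spacing[2]
  gz <- (seq_len(nd[3]) - 1) * target_mm / volume$spacing[3]
  x <- rep(gx, times = nd[2] * nd[3])
  y <- rep(rep(gy, each = nd[1]), times = nd[3])
  z <- rep(gz, each = nd[1] * nd[2])
  vals <- interp_trilinear(volume$data, x, y, z)
  as_volume(array(vals, dim = nd), spacing = rep(target_mm, 3),
            origin = volume$origin)
}

# 2x2x2 block averaging; edge blocks with fewer than 8 voxels average the
# voxels they do contain, so dims follow ceiling(d / 2).
block_downsample <- function(volume) {
  d <- dim(volume$data)
  nd <- as.integer(ceiling(d / 2))
  gi <- rep(seq_len(nd[1]), each = 2, length.out = d[1])
  gj <- rep(seq_len(nd[2]), each = 2, length.out = d[2])
  gk <- rep(seq_len(nd[3]), each = 2, length.out = d[3])
  s <- volume$data
  # sum + count along each axis in turn via rowsum on the unfolded array
  fold <- function(a, groups, axis) {
    dd <- dim(a)
    perm <- c(axis, setdiff(1:3, axis))
    m <- matrix(aperm(a, perm), nrow = dd[axis])
    sm <- rowsum(m, groups, reorder = TRUE)
    dd2 <- dd; dd2[axis] <- nrow(sm)
    aperm(array(sm, dim = dd2[perm]), order(perm))
  }
  sums <- fold(fold(fold(s, gi, 1), gj, 2), gk, 3)
  cnt <- outer(outer(tabulate(gi, nd[1]), tabulate(gj, nd[2])),
               tabulate(gk, nd[3]))
  new_origin <- volume$origin + volume$spacing / 2
  as_volume(sums / cnt, spacing = volume$spacing * 2, origin = new_origin)
}

#' Build the 8/4/2/1 mm multiresolution pyramid
#'
#' Starting from a 1 mm isotropic volume, successively applies 2x2x2 block
#' averaging to obtain the 2, 4 and 8 mm levels, matching the sub-sampling
#' scheme of the multiresolution affine search. Levels are ordered coarse to
#' fine.
#'
#' @param volume a 1 mm isotropic `volume` (checked to within 1e-6).
#' @return An object of class `pyramid`: a list with element `levels`
#'   (volumes at 8, 4, 2, 1 mm) and `mm = c(8, 4, 2, 1)`.
#' @export
build_pyramid <- function(volume) {
  volume <- as_volume(volume)
  if (any(abs(volume$spacing - 1) > 1e-6))
    stop("pyramid input must be 1 mm isotropic; call resample_isotropic() first")
  lev1 <- volume
  lev2 <- block_downsample(lev1)
  lev4 <- block_downsample(lev2)
  lev8 <- block_downsample(lev4)
  structure(list(levels = list(lev8, lev4, lev2, lev1), mm = c(8, 4, 2, 1)),
            class = "pyramid")
}

#' @export
print.pyramid <- function(x, ...) {
  cat("<pyramid>\n")
  for (i in seq_along(x$levels))
    cat(sprintf("  %d mm: %s\n", x$mm[i],
                paste(dim(x$levels[[i]]$data), collapse = "x")))
  invisible(x)
}
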