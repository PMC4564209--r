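# Sliding-window sum of width 2r+1 along the first dimension of a matrix,
# with edge replication. Implemented as a running (prefix) sum so each output
# reuses its neighbour's window: add the entering element, drop the leaving
# one — the incremental-reuse scheme, vectorized.
running_window_sum <- function(m, r) {
  n <- nrow(m)
  pad <- m[c(rep(1L, r), seq_len(n), rep(n, r)), , drop = FALSE]
  cs <- rbind(0, apply(pad, 2, cumsum))
  cs[(2L * r + 1L) + seq_len(n), , drop = FALSE] - cs[seq_len(n), , drop = FALSE]
}

# separable 3-D box sum over the (2r+1)^3 neighbourhood, edge-replicated
box_sum <- function(arr, r) {
  d <- dim(arr)
  for (axis in 1:3) {
    perm <- c(axis, setdiff(1:3, axis))
    m <- matrix(aperm(arr, perm), nrow = d[axis])
    m <- running_window_sum(m, r)
    arr <- aperm(array(m, dim = d[perm]), order(perm))
  }
  arr
}

#' Five local window sums
#'
#' For each voxel, sums the two images and their squares and cross-product
#' over the centred (2r+1)^3 neighbourhood: sum I_T, sum J_T, sum I_T^2,
#' sum J_T^2, sum I_T J_T. These five grids are everything the local
#' correlation and its A/B/C decomposition need. Sums are computed by
#' separable running sums (each window reuses its neighbour's, adding the
#' entering slab and dropping the leaving one) rather than fresh per-voxel
#' loops. The boundary is handled by edge replication so the window voxel
#' count n = (2r+1)^3 is constant everywhere.
#'
#' @param fixed fixed image I_T (`volume` or 3-D array).
#' @param moving_warped warped moving image J_T, same dimensions.
#' @param radius neighbourhood radius r in voxels, 1..8 (8 is the supported
#'   ceiling; 5 is the customary default).
#' @return An object of class `window_sums`: list of grids `s_i`, `s_j`,
#'   `s_ii`, `s_jj`, `s_ij` plus `radius` and `n` = (2r+1)^3.
#' @export
window_sums <- function(fixed, moving_warped, radius) {
  fi <- if (inherits(fixed, "volume")) fixed$data else as.array(fixed)
  mv <- if (inherits(moving_warped, "volume")) moving_warped$data else as.array(moving_warped)
  if (!identical(dim(fi), dim(mv))) stop("images must be co-dimensioned")
  radius <- as.integer(radius)
  if (radius < 1L || radius > 8L) stop("radius must be between 1 and 8 voxels")
  if (2L * radius >= min(dim(fi)))
    stop("radius exceeds half the smallest image dimension")
  structure(list(s_i = box_sum(fi, radius),
                 s_j = box_sum(mv, radius),
                 s_ii = box_sum(fi * fi, radius),
                 s_jj = box_sum(mv * mv, radius),
                 s_ij = box_sum(fi * mv, radius),
                 radius = radius,
                 n = (2 * radius + 1)^3),
            class = "window_sums")
}

#' Local means and the A/B/C intermediates
#'
#' From the five window sums, forms the local means m_I = (sum I_T)/n and
#' m_J = (sum J_T)/n and the three centred quantities
#' \deqn{A = \sum I_T^2 - 2 m_I \sum I_T + n m_I^2}
#' \deqn{B = \sum J_T^2 - 2 m_J \sum J_T + n m_J^2}
#' \deqn{C = \sum I_T J_T - m_I \sum J_T - m_J \sum I_T + n m_I m_J}
#' i.e. the windowed variances of each image (times n) and their covariance
#' (times n). Algebraically A = sum I^2 - (sum I)^2/n etc.; the expanded
#' forms above are evaluated literally.
#'
#' @param sums a `window_sums`.
#' @return An object of class `cc_intermediates`: grids `mean_i`, `mean_j`,
#'   `a`, `b`, `c`, plus `n`.
#' @export
cc_intermediates <- function(sums) {
  stopifnot(inherits(sums, "window_sums"))
  n <- sums$n
  mi <- sums$s_i / n
  mj <- sums$s_j / n
  a <- sums$s_ii - 2 * mi * sums$s_i + n * mi * mi
  b <- sums$s_jj - 2 * mj * sums$s_j + n * mj * mj
  cc <- sums$s_ij - mi * sums$s_j - mj * sums$s_i + n * mi * mj
  structure(list(mean_i = mi, mean_j = mj, a = a, b = b, c = cc, n = n),
            class = "cc_intermediates")
}

#' Local squared cross-correlation map
#'
#' CC(x) = C(x)^2 / (A(x) B(x)): the squared Pearson correlation of the two
#' images' values over the window at x, in [0, 1]. Voxels where either patch
#' is (numerically) flat carry no correlation signal: where A*B <= eps the
#' voxel is marked invalid and assigned 0.
#'
#' @param inter a `cc_intermediates`.
#' @param eps degeneracy threshold on A*B; default `1e-12 * n`.
#' @return An object of class `cc_map`: list with `cc` (grid in [0, 1]) and
#'   `valid` (logical grid).
#' @export
cc_map <- function(inter, eps = NULL) {
  stopifnot(inherits(inter, "cc_intermediates"))
  if (is.null(eps)) eps <- 1e-12 * inter$n
  ab <- inter$a * inter$b
  valid <- ab > eps
  cc <- array(0, dim(inter$a))
  cc[valid] <- pmin.int(pmax.int(inter$c[valid]^2 / ab[valid], 0), 1)
  structure(list(cc = cc, valid = valid), class = "cc_map")
}

#' Local CC map by per-voxel recomputation (oracle)
#'
#' Recomputes every voxel's local correlation from scratch over its
#' (edge-replicated) window with no shared sums — the independent reference
#' path for [window_sums()] + [cc_intermediates()] + [cc_map()]. Each voxel
#' is computed separately and independently of visitation order.
#'
#' @inheritParams window_sums
#' @param eps degeneracy threshold, as in [cc_map()].
#' @return A `cc_map`.
#' @export
cc_map_direct <- function(fixed, moving_warped, radius, eps = NULL) {
  fi <- if (inherits(fixed, "volume")) fixed$data else as.array(fixed)
  mv <- if (inherits(moving_warped, "volume")) moving_warped$data else as.array(moving_warped)
  if (!identical(dim(fi), dim(mv))) stop("images must be co-dimensioned")
  radius <- as.integer(radius)
  if (radius < 1L || radius > 8L) stop("radius must be between 1 and 8 voxels")
  if (2L * radius >= min(dim(fi)))
    stop("radius exceeds half the smallest image dimension")
  d <- dim(fi)
  n <- (2 * radius + 1)^3
  if (is.null(eps)) eps <- 1e-12 * n
  cc <- array(0, d)
  valid <- array(FALSE, d)
  off <- -radius:radius
  for (k in seq_len(d[3])) {
    kk <- pmin.int(pmax.int(k + off, 1L), d[3])
    for (j in seq_len(d[2])) {
      jj <- pmin.int(pmax.int(j + off, 1L), d[2])
      for (i in seq_len(d[1])) {
        ii <- pmin.int(pmax.int(i + off, 1L), d[1])
        wi <- fi[ii, jj, kk]
        wj <- mv[ii, jj, kk]
        dmi <- wi - mean(wi)
        dmj <- wj - mean(wj)
        a <- sum(dmi * dmi)
        b <- sum(dmj * dmj)
        if (a * b > eps) {
          valid[i, j, k] <- TRUE
          v <- sum(dmi * dmj)^2 / (a * b)
          cc[i, j, k] <- min(max(v, 0), 1)
        }
      }
    }
  }
  structure(list(cc = cc, valid = valid), class = "cc_map")
}

#' Mean local correlation
#'
#' Discretization of the CC data term: the mean of the local CC map over its
#' valid voxels, optionally restricted to a mask.
#'
#' @param cc a `cc_map`.
#' @param mask optional logical grid.
#' @return Scalar in [0, 1].
#' @export
mean_cc <- function(cc, mask = NULL) {
  stopifnot(inherits(cc, "cc_map"))
  sel <- cc$valid
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(sel))) stop("mask dimensions must match")
    sel <- sel & mask
  }
  if (!any(sel)) stop("no valid voxels to average over")
  mean(cc$cc[sel])
}
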