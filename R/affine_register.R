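#' Bins used at each pyramid resolution
#'
#' The affine search uses 256/n histogram bins at the n mm stage, i.e. 32,
#' 64, 128 and 256 bins at 8, 4, 2 and 1 mm.
#'
#' @param mm stage resolution in mm (8, 4, 2 or 1).
#' @return Integer bin count.
#' @export
stage_bins <- function(mm) {
  if (!mm %in% c(8, 4, 2, 1)) stop("stage resolution must be 8, 4, 2 or 1 mm")
  as.integer(256 / mm)
}

#' Search configuration for the affine registration
#'
#' @param dof degrees of freedom: 6 (rigid), 9 (+scales) or 12 (full affine,
#'   the default).
#' @param rot_range,rot_step half-range and step of the coarse rotation grid
#'   at 8 mm, radians (default +/-45 degrees in 15 degree steps per axis).
#' @param trans_range,trans_step half-range and step of the coarse
#'   translation grid, mm (default +/-16 mm in 8 mm steps).
#' @param n_keep number of best multistart candidates carried to the 4 mm
#'   stage (default 3).
#' @param max_sweeps cap on coordinate-descent sweeps per stage.
#' @param tol convergence tolerance on the cost decrease.
#' @param seed seed for any randomized restarts (the default search is
#'   deterministic).
#' @return A `search_config` list.
#' @export
search_config <- function(dof = 12, rot_range = pi / 4, rot_step = 15 * pi / 180,
                          trans_range = 16, trans_step = 8, n_keep = 3,
                          max_sweeps = 40, tol = 1e-7, seed = 0) {
  if (!dof %in% c(6, 9, 12)) stop("dof must be 6, 9 or 12")
  if (rot_range < 0 || rot_step <= 0 || trans_range < 0 || trans_step <= 0)
    stop("search ranges and steps must be positive")
  structure(list(dof = dof, rot_range = rot_range, rot_step = rot_step,
                 trans_range = trans_range, trans_step = trans_step,
                 n_keep = as.integer(n_keep), max_sweeps = as.integer(max_sweeps),
                 tol = tol, seed = seed),
            class = "search_config")
}

#' Registration cost: 1 - correlation ratio
#'
#' Samples the moving image through the candidate transform on the reference
#' grid, accumulates per-bin statistics via the stage's sorted index and
#' returns 1 - eta. Degenerate cases (no overlap, zero variance) return
#' `Inf`, a sentinel worst cost, so the search can continue past them.
#'
#' @param transform candidate `affine_transform`.
#' @param reference_level reference `volume` at the current stage.
#' @param moving moving `volume` (any resolution).
#' @param index `sorted_index` built from `reference_level`'s binning.
#' @param min_overlap smallest overlap fraction of the reference grid for
#'   which the cost is meaningful; below it the sentinel is returned (a tiny
#'   overlap can make the correlation ratio spuriously high).
#' @return Scalar cost in [0, 1], or `Inf`.
#' @export
cr_cost <- function(transform, reference_level, moving, index,
                    min_overlap = 0.2) {
  st <- sample_transformed(moving, transform, reference_level)
  if (mean(st$overlap) < min_overlap) return(Inf)
  stats <- accumulate_bin_stats(index, st$values, st$overlap)
  res <- tryCatch(correlation_ratio(stats), error = function(e) NULL)
  if (is.null(res)) return(Inf)
  1 - res$eta
}

# cost closure for one stage with cached voxel centers (the sorted index and
# the centers are fixed per stage; only the candidate transform varies)
make_stage_cost <- function(reference_level, moving_level, index,
                            min_overlap = 0.2) {
  centers <- voxel_centers(reference_level)
  dmov <- dim(moving_level$data)
  dref <- dim(reference_level$data)
  force(index)
  function(par, center) {
    tr <- affine_from_params(par, center)
    pts <- transform_points(tr, centers)
    cx <- (pts[, 1] - moving_level$origin[1]) / moving_level$spacing[1]
    cy <- (pts[, 2] - moving_level$origin[2]) / moving_level$spacing[2]
    cz <- (pts[, 3] - moving_level$origin[3]) / moving_level$spacing[3]
    overlap <- cx >= 0 & cx <= dmov[1] - 1 &
               cy >= 0 & cy <= dmov[2] - 1 &
               cz >= 0 & cz <= dmov[3] - 1
    if (mean(overlap) < min_overlap) return(Inf)
    vals <- interp_trilinear(moving_level$data, cx, cy, cz)
    vals[!overlap] <- 0
    stats <- accumulate_bin_stats(index, array(vals, dref),
                                  array(overlap, dref))
    res <- tryCatch(correlation_ratio(stats), error = function(e) NULL)
    if (is.null(res)) return(Inf)
    1 - res$eta
  }
}

# derivative-free coordinate descent with step halving; accepted moves are
# strictly cost-decreasing, so the accepted-cost trace never increases
local_optimize <- function(par, fn, active, steps, shrink = 0.5,
                           min_frac = 1 / 16, max_sweeps = 40, tol = 1e-7) {
  cur <- fn(par)
  trace <- cur
  min_steps <- steps * min_frac
  for (sweep in seq_len(max_sweeps)) {
    improved <- FALSE
    for (p in active) {
      for (dir in c(1, -1)) {
        cand <- par
        cand[p] <- cand[p] + dir * steps[p]
        cst <- fn(cand)
        if (is.finite(cst) && cst < cur - tol) {
          par <- cand; cur <- cst; trace <- c(trace, cur); improved <- TRUE
          break
        }
      }
    }
    if (!improved) {
      steps <- steps * shrink
      if (all(steps[active] < min_steps[active])) break
    }
  }
  list(par = par, cost = cur, trace = trace)
}

#' Multistart multiresolution affine registration
#'
#' Registers `moving` to `reference` by minimizing 1 - correlation ratio over
#' an 8/4/2/1 mm pyramid. Both volumes are resampled to 1 mm isotropic and
#' block-averaged into pyramids. At 8 mm a coarse multistart grid over
#' rotations and translations is evaluated and the best `n_keep` candidates
#' survive; each finer stage rebuilds its sorted intensity index once (with
#' 256/n bins at n mm), locally optimizes the surviving candidates by
#' coordinate descent with step halving, and passes the best forward. The
#' returned transform maps reference world coordinates into moving world
#' coordinates.
#'
#' @param reference reference `volume` I.
#' @param moving moving `volume` J.
#' @param config a [search_config()].
#' @return List with `transform` (the 1 mm winner), `params` (its 12
#'   parameters about the reference center), `center`, and `trace` (per-stage
#'   list of mm, bins, index builds, candidate costs and the accepted-cost
#'   trace of the local optimization).
#' @export
register_affine <- function(reference, moving, config = search_config()) {
  reference <- as_volume(reference)
  moving <- as_volume(moving)
  ref1 <- if (all(abs(reference$spacing - 1) < 1e-6)) reference else
    resample_isotropic(reference, 1)
  mov1 <- if (all(abs(moving$spacing - 1) < 1e-6)) moving else
    resample_isotropic(moving, 1)
  pyr_ref <- build_pyramid(ref1)
  pyr_mov <- build_pyramid(mov1)
  center <- volume_center(ref1)
  # initialize translation by aligning volume centers
  t0 <- volume_center(mov1) - center
  base_par <- c(t0, 0, 0, 0, 1, 1, 1, 0, 0, 0)

  lever <- max(dim(ref1$data) * ref1$spacing) / 2
  active <- seq_len(config$dof)
  trace <- list()

  # --- 8 mm multistart grid (rigid subset) ---
  ref8 <- pyr_ref$levels[[1]]; mov8 <- pyr_mov$levels[[1]]
  index_builds <- 0L
  binned8 <- bin_reference(ref8, stage_bins(8))
  idx8 <- build_sorted_index(binned8); index_builds <- index_builds + 1L
  cost8 <- make_stage_cost(ref8, mov8, idx8)
  rots <- seq(-config$rot_range, config$rot_range, by = config$rot_step)
  trs <- seq(-config$trans_range, config$trans_range, by = config$trans_step)
  grid <- expand.grid(tx = t0[1] + trs, ty = t0[2] + trs, tz = t0[3] + trs,
                      rx = rots, ry = rots, rz = rots,
                      KEEP.OUT.ATTRS = FALSE)
  gcosts <- numeric(nrow(grid))
  gm <- as.matrix(grid)
  for (g in seq_len(nrow(gm))) {
    par <- base_par
    par[1:6] <- gm[g, ]
    gcosts[g] <- cost8(par, center)
  }
  keep <- order(gcosts)[seq_len(min(config$n_keep, nrow(gm)))]
  candidates <- lapply(keep, function(g) {
    par <- base_par; par[1:6] <- gm[g, ]; list(par = par, cost = gcosts[g])
  })
  # always carry the centre-aligned initial pose as an extra survivor: at
  # coarse resolutions the per-bin statistics are thin and the grid winner
  # can be an overfit pose
  candidates <- c(candidates, list(list(par = base_par,
                                        cost = cost8(base_par, center))))
  if (!any(is.finite(gcosts)))
    stop("no candidate produced a finite cost at 8 mm: volumes may not overlap")
  trace[["8mm"]] <- list(mm = 8, bins = stage_bins(8),
                         index_builds = index_builds,
                         n_evaluated = nrow(gm),
                         best_costs = gcosts[keep])

  # --- finer stages: local optimization ---
  for (li in 2:4) {
    mm <- pyr_ref$mm[li]
    refl <- pyr_ref$levels[[li]]; movl <- pyr_mov$levels[[li]]
    index_builds <- 0L
    binned <- bin_reference(refl, stage_bins(mm))
    idx <- build_sorted_index(binned); index_builds <- index_builds + 1L
    costf <- make_stage_cost(refl, movl, idx)
    steps <- c(rep(mm, 3), rep(mm / lever, 3), rep(mm / lever, 3),
               rep(mm / lever, 3))
    opt <- lapply(candidates, function(cand)
      local_optimize(cand$par, function(p) costf(p, center), active, steps,
                     max_sweeps = config$max_sweeps, tol = config$tol))
    costs <- vapply(opt, `[[`, numeric(1), "cost")
    best <- which.min(costs)
    trace[[paste0(mm, "mm")]] <- list(mm = mm, bins = stage_bins(mm),
                                      index_builds = index_builds,
                                      candidate_costs = costs,
                                      cost_trace = opt[[best]]$trace)
    candidates <- opt[best]  # pass the best forward
  }
  final <- candidates[[1]]
  tr <- affine_from_params(final$par, center)
  list(transform = tr, params = final$par, center = center, trace = trace,
       cost = final$cost)
}

#' Resample a moving volume through an affine transform
#'
#' Returns the moving image evaluated on the reference grid through the
#' transform (trilinear; voxels mapping outside the moving extent become 0).
#'
#' @inheritParams cr_cost
#' @return A `volume` on the reference grid.
#' @export
resample_affine <- function(moving, transform, reference) {
  st <- sample_transformed(moving, transform, reference)
  as_volume(st$values, reference$spacing, reference$origin)
}
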