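#' Mean absolute difference between two volumes
#'
#' Voxelwise mean of |a - b|, the intensity-based registration accuracy
#' measure used to compare registered results against a reference.
#'
#' @param a,b co-dimensioned `volume`s (or arrays).
#' @param mask optional logical grid restricting the average.
#' @return Scalar MAD.
#' @export
mad_volumes <- function(a, b, mask = NULL) {
  av <- if (inherits(a, "volume")) a$data else as.array(a)
  bv <- if (inherits(b, "volume")) b$data else as.array(b)
  if (!identical(dim(av), dim(bv))) stop("volumes must be co-dimensioned")
  dif <- abs(av - bv)
  if (is.null(mask)) return(mean(dif))
  if (!identical(dim(mask), dim(av))) stop("mask dimensions must match")
  if (!any(mask)) stop("empty mask")
  mean(dif[mask])
}

#' Jaccard overlap of two label volumes
#'
#' For every foreground label present in either volume, computes
#' J = |A intersect B| / |A union B| over its voxel sets. Labels absent from
#' both volumes are omitted; a label present in only one scores 0.
#'
#' @param a,b co-dimensioned `label_volume`s (or integer arrays).
#' @return An `overlap_report`: data frame with columns `label`,
#'   `intersection`, `union`, `jaccard`, plus attribute `mean_jaccard` (mean
#'   over foreground labels).
#' @export
jaccard <- function(a, b) {
  av <- if (inherits(a, "volume")) a$data else as.array(a)
  bv <- if (inherits(b, "volume")) b$data else as.array(b)
  if (!identical(dim(av), dim(bv))) stop("label volumes must be co-dimensioned")
  labs <- sort(setdiff(union(unique(as.vector(av)), unique(as.vector(bv))), 0))
  if (length(labs) == 0) stop("no foreground labels in either volume")
  inter <- uni <- integer(length(labs))
  for (i in seq_along(labs)) {
    in_a <- av == labs[i]; in_b <- bv == labs[i]
    inter[i] <- sum(in_a & in_b)
    uni[i] <- sum(in_a | in_b)
  }
  rep_df <- data.frame(label = labs, intersection = inter, union = uni,
                       jaccard = inter / uni)
  structure(rep_df, mean_jaccard = mean(rep_df$jaccard),
            class = c("overlap_report", "data.frame"))
}

#' @export
print.overlap_report <- function(x, ...) {
  print.data.frame(x, row.names = FALSE)
  cat(sprintf("mean Jaccard over foreground labels: %.6f\n",
              attr(x, "mean_jaccard")))
  invisible(x)
}

#' Carry labels through a recovered transform
#'
#' Resamples a label volume onto the reference grid through an affine
#' transform or a displacement field, using nearest-neighbour interpolation;
#' voxels mapping outside the label volume become background (0).
#'
#' @param labels a `label_volume`.
#' @param transform an `affine_transform` or `displacement_field` (reference
#'   -> label-volume space).
#' @param reference `volume` defining the output grid.
#' @return A `label_volume` on the reference grid.
#' @export
transform_labels <- function(labels, transform, reference) {
  labels <- as_label_volume(labels)
  reference <- as_volume(reference)
  d <- dim(reference$data)
  if (inherits(transform, "affine_transform")) {
    pts <- transform_points(transform, voxel_centers(reference))
  } else if (inherits(transform, "displacement_field")) {
    if (!identical(dim(transform$u)[1:3], d))
      stop("field grid must match the reference")
    pts <- voxel_centers(reference) + matrix(transform$u, ncol = 3)
  } else stop("transform must be an affine_transform or displacement_field")
  cx <- (pts[, 1] - labels$origin[1]) / labels$spacing[1]
  cy <- (pts[, 2] - labels$origin[2]) / labels$spacing[2]
  cz <- (pts[, 3] - labels$origin[3]) / labels$spacing[3]
  vals <- interp_nearest(labels$data, cx, cy, cz, outside = 0)
  as_label_volume(array(as.integer(round(vals)), d), reference$spacing,
                  reference$origin)
}
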