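# small random volumes and fixtures, generated in code under fixed seeds

random_volume <- function(dims, spacing = c(1, 1, 1), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  as_volume(array(stats::rnorm(prod(dims)), dims), spacing = spacing)
}

# a random reference/values/overlap instance for CR checks
random_cr_instance <- function(dims, n_bins, seed) {
  set.seed(seed)
  ref <- array(stats::runif(prod(dims), 0, 100), dims)
  vals <- 0.4 * ref + array(stats::rnorm(prod(dims), sd = 10), dims)
  overlap <- array(stats::runif(prod(dims)) > 0.15, dims)
  if (!any(overlap)) overlap[1] <- TRUE
  list(binned = bin_reference(ref, n_bins), values = vals, overlap = overlap)
}

# rotation angle (degrees) between the linear parts of two transforms
rotation_error_deg <- function(a, b) {
  ra <- a$matrix[1:3, 1:3]; rb <- b$matrix[1:3, 1:3]
  # polar-decompose to strip any scale component before comparing
  pol <- function(m) { s <- svd(m); s$u %*% t(s$v) }
  d <- t(pol(ra)) %*% pol(rb)
  acos(min(1, max(-1, (sum(diag(d)) - 1) / 2))) * 180 / pi
}
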