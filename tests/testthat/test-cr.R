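test_that("binning maps intensities to the expected bins", {
  v <- array(0:255, c(16, 16, 1))
  b <- bin_reference(v, 256)
  expect_identical(b$bin_of_voxel[, , 1], matrix(0:255, 16, 16))
  expect_false(b$degenerate)

  const <- bin_reference(array(5, c(4, 4, 4)), 16)
  expect_true(const$degenerate)
  expect_true(all(const$bin_of_voxel == 0L))

  # values spanning [0, 1): 0.74 * 4 bins -> bin 2
  vals <- array(c(0, 0.25, 0.5, 0.74, 0.9999, rep(0.1, 22)), c(27, 1, 1))
  b4 <- bin_reference(vals, 4)
  expect_equal(b4$bin_of_voxel[4, 1, 1], 2L)

  expect_error(bin_reference(v, 256, mask = array(FALSE, dim(v))), "mask")
  expect_error(bin_reference(v, 1), "n_bins")
})

test_that("sorted index is a stable bin-contiguous permutation", {
  # bins per voxel (linear order) 2,0,1,0 -> voxel order 2,4,3,1 (1-based)
  b <- bin_reference(array(c(2, 0, 1, 0), c(4, 1, 1)), 3)
  idx <- build_sorted_index(b)
  expect_identical(idx$voxel, c(2L, 4L, 3L, 1L))
  expect_identical(idx$bin_start, c(1L, 3L, 4L))
  expect_identical(idx$bin_end, c(3L, 4L, 5L))

  # all voxels in one bin: original linear order preserved (stability)
  one <- bin_reference(array(1:8 * 0 + 3, c(2, 2, 2)), 4)
  expect_identical(build_sorted_index(one)$voxel, 1:8)

  # random volume: concatenated bins are a permutation of all voxels,
  # contiguous per bin
  set.seed(9)
  r <- array(runif(1000), c(10, 10, 10))
  bi <- bin_reference(r, 32)
  ix <- build_sorted_index(bi)
  expect_identical(sort(ix$voxel), 1:1000)
  expect_true(all(diff(ix$bin) >= 0))
  counts <- ix$bin_end - ix$bin_start
  expect_identical(as.integer(sum(counts)), 1000L)
})

test_that("sampling through a transform respects overlap geometry", {
  v <- random_volume(c(16, 16, 16), seed = 10)
  st <- sample_transformed(v, affine_identity(), v)
  expect_true(all(st$overlap))
  expect_equal(st$values, v$data)

  # translate by half the field of view along x
  half <- affine_from_params(c(7.5, 0, 0))
  sh <- sample_transformed(v, half, v)
  expect_equal(mean(sh$overlap), 0.5, tolerance = 0.05)

  # push fully outside: empty overlap, cost sentinel
  far <- affine_from_params(c(100, 0, 0))
  sf <- sample_transformed(v, far, v)
  expect_false(any(sf$overlap))
  b <- bin_reference(v, 16)
  expect_identical(cr_cost(far, v, v, build_sorted_index(b)), Inf)
})

test_that("bin statistics accumulate correctly and are partition invariant", {
  b <- bin_reference(array(1, c(3, 1, 1)) * c(1, 1, 1), 2)  # degenerate: 1 bin
  idx <- build_sorted_index(b)
  st <- accumulate_bin_stats(idx, array(c(1, 2, 3), c(3, 1, 1)),
                             array(TRUE, c(3, 1, 1)))
  expect_equal(st$count[1], 3)
  expect_equal(st$sum[1], 6)
  expect_equal(st$sum_sq[1], 14)

  ov <- array(c(TRUE, FALSE, TRUE), c(3, 1, 1))
  st2 <- accumulate_bin_stats(idx, array(c(1, 2, 3), c(3, 1, 1)), ov)
  expect_equal(st2$count[1], 2)
  expect_equal(st2$sum[1], 4)
  expect_equal(st2$sum_sq[1], 10)

  inst <- random_cr_instance(c(12, 12, 12), 32, seed = 11)
  ix <- build_sorted_index(inst$binned)
  s1 <- accumulate_bin_stats(ix, inst$values, inst$overlap, 1)
  s4 <- accumulate_bin_stats(ix, inst$values, inst$overlap, 4)
  s13 <- accumulate_bin_stats(ix, inst$values, inst$overlap, 13)
  expect_identical(s1, s4)
  expect_identical(s1, s13)
})

test_that("correlation ratio reproduces hand-computed values", {
  b <- bin_reference(array(c(0, 0, 1, 1), c(4, 1, 1)), 2)
  idx <- build_sorted_index(b)
  ov <- array(TRUE, c(4, 1, 1))

  st <- accumulate_bin_stats(idx, array(c(1, 2, 3, 5), c(4, 1, 1)), ov)
  r <- correlation_ratio(st)
  expect_equal(r$eta, 1 - 2.5 / 8.75, tolerance = 1e-12)
  expect_equal(r$n_overlap, 4)

  # conditional distributions equal the marginal: eta = 0
  st0 <- accumulate_bin_stats(idx, array(c(0, 1, 0, 1), c(4, 1, 1)), ov)
  expect_equal(correlation_ratio(st0)$eta, 0, tolerance = 0)

  # deterministic dependence: eta = 1
  set.seed(12)
  a <- array(sample(0:255, 16^3, TRUE), c(16, 16, 16))
  ba <- bin_reference(a, 256)
  sa <- accumulate_bin_stats(build_sorted_index(ba), a, array(TRUE, dim(a)))
  expect_equal(correlation_ratio(sa)$eta, 1, tolerance = 0)

  # zero variance is an error
  stz <- accumulate_bin_stats(idx, array(2, c(4, 1, 1)), ov)
  expect_error(correlation_ratio(stz), "variance")
})

test_that("sorted-index path agrees with the direct-grouping oracle", {
  worst <- 0
  for (s in 1:20) {
    dims <- rep(sample(8:16, 1), 3)
    inst <- random_cr_instance(dims, sample(c(8, 32, 64), 1), seed = 200 + s)
    ix <- build_sorted_index(inst$binned)
    st <- accumulate_bin_stats(ix, inst$values, inst$overlap)
    eta <- correlation_ratio(st)$eta
    eta_d <- correlation_ratio_direct(inst$binned, inst$values, inst$overlap)
    worst <- max(worst, abs(eta - eta_d) / max(eta_d, 1e-12))
  }
  expect_lt(worst, 1e-10)

  # permuting storage order leaves the direct oracle unchanged
  inst <- random_cr_instance(c(8, 8, 8), 16, seed = 42)
  eta1 <- correlation_ratio_direct(inst$binned, inst$values, inst$overlap)
  set.seed(1); perm <- sample(512)
  b2 <- inst$binned
  b2$bin_of_voxel <- array(inst$binned$bin_of_voxel[perm], dim = c(8, 8, 8))
  eta2 <- correlation_ratio_direct(b2, array(inst$values[perm], c(8, 8, 8)),
                                   array(inst$overlap[perm], c(8, 8, 8)))
  expect_equal(eta1, eta2, tolerance = 1e-12)
})

test_that("eta stays within [0, 1] and detects within-bin constancy", {
  for (s in 1:15) {
    inst <- random_cr_instance(rep(sample(6:10, 1), 3), 16, seed = 300 + s)
    ix <- build_sorted_index(inst$binned)
    st <- accumulate_bin_stats(ix, inst$values, inst$overlap)
    eta <- correlation_ratio(st)$eta
    expect_gte(eta, 0)
    expect_lte(eta, 1)
    # law of total variance: within-bin scatter cannot exceed the total
    n <- sum(st$count)
    m <- sum(st$sum) / n
    tot <- sum(st$sum_sq) / n - m^2
    nz <- st$count > 1
    within <- sum(st$sum_sq[nz] - st$sum[nz]^2 / st$count[nz])
    expect_lte(within, n * tot * (1 + 1e-9))
  }

  # values constant within every occupied bin -> eta exactly 1
  set.seed(77)
  ref <- array(runif(512), c(8, 8, 8))
  b <- bin_reference(ref, 8)
  vals <- array(as.numeric(b$bin_of_voxel) * 3 - 1, c(8, 8, 8))
  st <- accumulate_bin_stats(build_sorted_index(b), vals, array(TRUE, c(8, 8, 8)))
  expect_equal(correlation_ratio(st)$eta, 1, tolerance = 0)
})
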