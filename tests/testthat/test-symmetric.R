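test_that("warping through a field shifts values as expected", {
  v <- random_volume(c(12, 12, 12), seed = 40)
  expect_equal(warp(v, voxalign:::zero_field(v))$data, v$data)

  ramp <- as_volume(array(rep(0:15, 16 * 16), c(16, 16, 16)))
  fld <- displacement_field(array(rep(c(1, 0, 0), each = 16^3), c(16, 16, 16, 3)))
  w <- warp(ramp, fld)
  expect_lt(max(abs(w$data[1:15, , ] - ramp$data[2:16, , ])), 1e-9)

  # zero-field warp leaves the local correlation against the original at 1
  cm <- cc_map(cc_intermediates(window_sums(
    warp(v, voxalign:::zero_field(v)), v, 2)))
  expect_equal(mean_cc(cm), 1, tolerance = 1e-9)

  bad <- displacement_field(dims = c(4, 4, 4))
  expect_error(warp(v, bad), "grid")
})

test_that("a symmetric step is a no-op at a fixed point or zero step", {
  ph <- make_phantom(phantom_spec(size = 24, seed = 41, noise_sd = 0.5))
  v <- ph$volume
  z1 <- voxalign:::zero_field(v); z2 <- voxalign:::zero_field(v)
  cfg <- sym_config()
  res <- symmetric_step(v, v, z1, z2, cfg)
  expect_false(res$accepted)
  expect_equal(res$mean_cc, 1, tolerance = 1e-9)
  expect_identical(res$phi1$u, z1$u)

  res0 <- symmetric_step(v, warp(v, z1), z1, z2, cfg, step_voxels = 0)
  expect_false(res0$accepted)
  expect_identical(res0$phi2$u, z2$u)
})

test_that("accepted steps monotonically improve mean CC on a deformed phantom", {
  ph <- make_phantom(phantom_spec(size = 32, seed = 42, noise_sd = 0.5))
  df <- apply_known_deformation(ph$volume, NULL, amplitude_mm = 2,
                                sigma_mm = 6, seed = 43)
  cfg <- sym_config(iterations = 10, levels = 1)
  phi1 <- voxalign:::zero_field(ph$volume)
  phi2 <- voxalign:::zero_field(ph$volume)
  trace <- numeric(0)
  step <- cfg$step_voxels
  for (i in 1:10) {
    res <- symmetric_step(ph$volume, df$volume, phi1, phi2, cfg, step)
    if (res$accepted) {
      phi1 <- res$phi1; phi2 <- res$phi2
      trace <- c(trace, res$mean_cc)
    } else step <- step / 2
  }
  expect_gt(length(trace), 3)
  expect_true(all(diff(trace) > 0))
})

test_that("field inversion and composition are mutually consistent", {
  ph <- make_phantom(phantom_spec(size = 24, seed = 44, noise_sd = 0))
  df <- apply_known_deformation(ph$volume, NULL, amplitude_mm = 2,
                                sigma_mm = 6, seed = 45)
  inv <- voxalign:::invert_field(df$field)
  resid <- voxalign:::compose_fields(inv, df$field)
  expect_lt(max(abs(resid$u)), 2e-2)  # mm

  const <- displacement_field(array(rep(c(1.5, -0.5, 0), each = 24^3),
                                    c(24, 24, 24, 3)))
  cinv <- voxalign:::invert_field(const)
  expect_lt(max(abs(cinv$u[, , , 1] + 1.5)), 1e-9)
})

test_that("registering a volume to itself is (near) a fixed point", {
  ph <- make_phantom(phantom_spec(size = 24, seed = 46, noise_sd = 0.5))
  res <- register_symmetric(ph$volume, ph$volume,
                            config = sym_config(iterations = 5, levels = 1))
  expect_gte(res$mean_cc, 0.999)
  expect_lt(max(abs(res$field$u)), 0.25)  # mm; essentially no net warp
})

test_that("swapping reference and moving yields an equivalent warped pair", {
  ph <- make_phantom(phantom_spec(size = 32, seed = 47, noise_sd = 0.5))
  df <- apply_known_deformation(ph$volume, NULL, amplitude_mm = 2,
                                sigma_mm = 6, seed = 48)
  cfg <- sym_config(iterations = 15, levels = 1)
  fwd <- register_symmetric(ph$volume, df$volume, config = cfg)
  rev <- register_symmetric(df$volume, ph$volume, config = cfg)
  # the MAD between the two half-way warped images is the swap-invariant
  # quantity: both runs drive the same pair toward the same midpoint
  mad_fwd <- mad_volumes(warp(ph$volume, fwd$phi1), warp(df$volume, fwd$phi2))
  mad_rev <- mad_volumes(warp(df$volume, rev$phi1), warp(ph$volume, rev$phi2))
  expect_lt(abs(mad_fwd - mad_rev) / max(mad_fwd, mad_rev), 0.10)
  # and both improve on the unregistered pair
  pre <- mad_volumes(df$volume, ph$volume)
  expect_lt(mad_fwd, pre)
  expect_lt(mad_rev, pre)
})

test_that("displacement fields round-trip through NIfTI", {
  set.seed(49)
  u <- array(rnorm(6 * 6 * 6 * 3), c(6, 6, 6, 3))
  f <- displacement_field(u, spacing = c(1, 1.5, 2))
  path <- tempfile(fileext = ".nii.gz")
  write_field(f, path)
  g <- read_field(path)
  expect_equal(g$u, f$u)
  expect_equal(g$spacing, f$spacing)
})
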