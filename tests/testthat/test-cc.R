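test_that("window sums match the (2r+1)^3 window with edge replication", {
  const <- array(2, c(8, 8, 8))
  ws <- window_sums(const, const, 1)
  expect_true(all(ws$s_i == 54))   # 27 voxels x 2
  expect_equal(ws$n, 27)

  imp <- array(0, c(9, 9, 9)); imp[5, 5, 5] <- 1
  wi <- window_sums(imp, imp, 1)
  inside <- wi$s_i[3:7, 3:7, 3:7]
  expect_equal(sum(wi$s_i), sum(inside))
  expect_true(all(wi$s_i[4:6, 4:6, 4:6] == 1))
  expect_equal(sum(wi$s_i == 1), 27)

  # all five grids against a brute-force window oracle
  set.seed(20)
  f <- array(rnorm(12^3), c(12, 12, 12))
  m <- array(rnorm(12^3), c(12, 12, 12))
  ws2 <- window_sums(f, m, 2)
  brute <- function(a, b) {
    d <- dim(a); out <- array(0, d)
    for (k in 1:d[3]) for (j in 1:d[2]) for (i in 1:d[1]) {
      ii <- pmin(pmax(i + (-2:2), 1), d[1])
      jj <- pmin(pmax(j + (-2:2), 1), d[2])
      kk <- pmin(pmax(k + (-2:2), 1), d[3])
      out[i, j, k] <- sum(a[ii, jj, kk] * b[ii, jj, kk])
    }
    out
  }
  rel <- function(x, y) max(abs(x - y)) / max(abs(y))
  expect_lt(rel(ws2$s_ij, brute(f, m)), 1e-9)
  expect_lt(rel(ws2$s_ii, brute(f, f)), 1e-9)
  expect_lt(rel(ws2$s_i, brute(f, array(1, dim(f)))), 1e-9)

  expect_error(window_sums(f, m, 0), "radius")
  expect_error(window_sums(f, m, 9), "radius")
  expect_error(window_sums(array(0, c(5, 5, 5)), array(0, c(5, 5, 5)), 3),
               "smallest")
})

test_that("A/B/C intermediates obey their algebraic identities", {
  set.seed(21)
  f <- array(rnorm(10^3, sd = 3), c(10, 10, 10))
  m <- array(rnorm(10^3, sd = 3), c(10, 10, 10))
  ws <- window_sums(f, m, 2)
  it <- cc_intermediates(ws)
  n <- ws$n
  rel <- function(x, y) max(abs(x - y)) / max(1e-12, max(abs(y)))
  expect_lt(rel(it$a, ws$s_ii - ws$s_i^2 / n), 1e-9)
  expect_lt(rel(it$b, ws$s_jj - ws$s_j^2 / n), 1e-9)
  expect_lt(rel(it$c, ws$s_ij - ws$s_i * ws$s_j / n), 1e-9)
  expect_true(all(it$a >= -1e-9))
  expect_true(all(it$b >= -1e-9))
  # Cauchy-Schwarz within numerical slack
  expect_true(all(it$c^2 <= it$a * it$b * (1 + 1e-9) + 1e-9))

  # identical inputs: A == B == C
  ws_id <- window_sums(f, f, 1)
  it_id <- cc_intermediates(ws_id)
  expect_equal(it_id$a, it_id$b)
  expect_equal(it_id$a, it_id$c)

  # constant fixed image: A = 0 everywhere
  it_const <- cc_intermediates(window_sums(array(4, c(8, 8, 8)), f[1:8, 1:8, 1:8], 1))
  expect_lt(max(abs(it_const$a)), 1e-9)
})

test_that("cc map is 1 for affinely related images and 0 on flat patches", {
  set.seed(22)
  f <- array(rnorm(10^3), c(10, 10, 10))
  cm <- cc_map(cc_intermediates(window_sums(f, f, 2)))
  expect_true(all(cm$valid))
  expect_equal(max(abs(cm$cc - 1)), 0, tolerance = 1e-8)

  cm2 <- cc_map(cc_intermediates(window_sums(f, 3 * f + 7, 2)))
  expect_equal(max(abs(cm2$cc - 1)), 0, tolerance = 1e-8)

  flat <- array(5, c(10, 10, 10))
  cm3 <- cc_map(cc_intermediates(window_sums(f, flat, 2)))
  expect_false(any(cm3$valid))
  expect_true(all(cm3$cc == 0))
})

test_that("sums-based cc map matches the per-voxel oracle", {
  worst <- 0
  for (s in 1:10) {
    r <- ((s - 1) %% 3) + 1
    set.seed(400 + s)
    f <- array(rnorm(1000), c(10, 10, 10))
    m <- array(0.5 * f + rnorm(1000, sd = 0.8), c(10, 10, 10))
    fast <- cc_map(cc_intermediates(window_sums(f, m, r)))
    slow <- cc_map_direct(f, m, r)
    worst <- max(worst, max(abs(fast$cc - slow$cc)))
  }
  expect_lt(worst, 1e-8)
})

test_that("cc is symmetric in its two images and bounded", {
  set.seed(23)
  f <- array(rnorm(8^3), c(8, 8, 8))
  m <- array(rnorm(8^3), c(8, 8, 8))
  a <- cc_map(cc_intermediates(window_sums(f, m, 2)))
  b <- cc_map(cc_intermediates(window_sums(m, f, 2)))
  expect_equal(a$cc, b$cc, tolerance = 1e-10)
  expect_true(all(a$cc >= 0 & a$cc <= 1))
})

test_that("mean_cc averages valid voxels and honours masks", {
  set.seed(24)
  f <- array(rnorm(8^3), c(8, 8, 8))
  m <- array(rnorm(8^3), c(8, 8, 8))
  cm <- cc_map(cc_intermediates(window_sums(f, m, 1)))
  expect_equal(mean_cc(cm), mean(cm$cc[cm$valid]))
  expect_equal(mean_cc(cc_map(cc_intermediates(window_sums(f, f, 1)))), 1,
               tolerance = 1e-9)

  mask <- array(FALSE, c(8, 8, 8)); mask[4, 4, 4] <- TRUE
  expect_equal(mean_cc(cm, mask), cm$cc[4, 4, 4])
  expect_error(mean_cc(cm, array(FALSE, c(8, 8, 8))), "valid")
})
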