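test_that("kalman_smooth follows the scalar constant-state recursion", {
  # fixed point: constant input with matching prior stays put
  expect_equal(kalman_smooth(rep(3.2, 20), q = 0.01, r = 0.1, x0 = 3.2),
               rep(3.2, 20))
  # r -> 0 drives the gain to 1: estimates track the measurements
  z <- c(0, 5, -2, 7, 7, 1)
  est <- kalman_smooth(z, q = 1, r = 1e-12, x0 = 0, p0 = 1)
  expect_equal(est[-1], z[-1], tolerance = 1e-6)
  # hand-unrolled two-step recursion: q=r=p0=1, x0=0, series (0, 1):
  # step 1: p-=2, k=2/3, x=0;  step 2: p-=5/3, k=5/8, x=5/8
  expect_equal(kalman_smooth(c(0, 1), q = 1, r = 1, x0 = 0, p0 = 1),
               c(0, 5 / 8))
  # independent straight-line transcription on a random series
  set.seed(42)
  z <- rnorm(25)
  oracle <- local({
    x <- 0; p <- 1; out <- numeric(25)
    for (i in 1:25) {
      p_pred <- p + 0.3
      gain <- p_pred / (p_pred + 0.7)
      x <- x + gain * (z[i] - x)
      p <- (1 - gain) * p_pred
      out[i] <- x
    }
    out
  })
  expect_equal(kalman_smooth(z, q = 0.3, r = 0.7, x0 = 0, p0 = 1), oracle)
})

test_that("kalman_smooth rejects degenerate input", {
  expect_error(kalman_smooth(numeric(0), q = 1, r = 1), "non-empty")
  expect_error(kalman_smooth(c(1, 2), q = 0, r = 1), "positive")
  expect_error(kalman_smooth(c(1, 2), q = 1, r = -1), "positive")
})

test_that("kalman_smooth reduces white-noise variance", {
  set.seed(77)
  z <- rnorm(1e4)
  est <- kalman_smooth(z, q = 0.01, r = 0.1, x0 = 0, p0 = 1)
  expect_lt(var(est), var(z))
})

test_that("normalization divides by the fixed full scale and clips", {
  tr <- data.frame(t = 0:2 / 100, ax = c(32768L, 0L, -16384L),
                   ay = c(0L, 0L, 0L), az = c(0L, 32768L, 0L))
  norm <- normalize_counts(tr)
  expect_equal(norm$ax, c(1, 0, -0.5))
  expect_equal(norm$az, c(0, 1, 0))
  expect_true(all(abs(as.matrix(norm[c("ax", "ay", "az")])) <= 1))
})

test_that("levelize applies the strict +/- threshold band", {
  expect_identical(levelize(0.5), 1L)
  expect_identical(levelize(0.35), 0L)   # boundary is not 'greater than'
  expect_identical(levelize(-0.35), 0L)
  expect_identical(levelize(-0.36), -1L)
  grid <- seq(-1, 1, by = 0.01)
  lev <- levelize(grid)
  expect_true(all(lev %in% c(-1L, 0L, 1L)))
  expect_equal(levelize(-grid), -lev)          # odd function
  expect_true(all(diff(lev) >= 0))             # monotone non-decreasing
})

test_that("preprocess_trace is length-preserving, causal, and handles rest states", {
  n <- 120
  gravity <- data.frame(t = (0:(n - 1)) / 100,
                        ax = 0L, ay = 0L, az = as.integer(round(0.9 * 32768)))
  lev <- preprocess_trace(gravity)
  expect_equal(nrow(lev), n)
  expect_true(all(lev$lx == 0 & lev$ly == 0 & lev$lz == 1))
  zero <- data.frame(t = (0:9) / 100, ax = 0L, ay = 0L, az = 0L)
  lz <- preprocess_trace(zero)
  expect_true(all(lz$lx == 0 & lz$ly == 0 & lz$lz == 0))
  # causality: the leveled prefix does not depend on later samples
  set.seed(5)
  noisy <- data.frame(t = (0:99) / 100,
                      ax = as.integer(rnorm(100, 0, 3000)),
                      ay = as.integer(rnorm(100, -20000, 3000)),
                      az = as.integer(rnorm(100, 0, 3000)))
  full <- preprocess_trace(noisy)
  prefix <- preprocess_trace(noisy[1:40, ])
  expect_equal(prefix, full[1:40, ])
})

test_that("preprocess_trace reproduces the generator's clean step-1 run classes", {
  thr <- generate_throw(throw_profile(noise_sigma = 0))
  pair <- pipeline_pair(thr)
  s1 <- thr$truth$step_bounds[1, ]
  seg <- substr(pair$forearm, s1$start, s1$end)
  runs <- compress_runs(seg)
  expect_true(all(c("E", "P") %in% runs$symbols))
  # E precedes P as the wind-up sequence requires
  expect_lt(match("E", runs$symbols), match("P", runs$symbols))
})

test_that("invalid raw traces are rejected with informative errors", {
  ok <- data.frame(t = 0:1 / 100, ax = 0L, ay = 0L, az = 0L)
  bad_t <- ok; bad_t$t <- c(0.02, 0.01)
  expect_error(preprocess_trace(bad_t), "monotone")
  bad_range <- ok; bad_range$ax <- c(0L, 40000L)
  expect_error(preprocess_trace(bad_range), "outside")
  bad_na <- ok; bad_na$ay[1] <- NA
  expect_error(preprocess_trace(bad_na), "missing")
})
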