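test_that("generation is reproducible under a fixed seed", {
  a <- generate_throw(throw_profile(noise_sigma = 0.1, seed = 21))
  b <- generate_throw(throw_profile(noise_sigma = 0.1, seed = 21))
  expect_identical(a$forearm, b$forearm)
  expect_identical(a$upperarm, b$upperarm)
  c <- generate_throw(throw_profile(noise_sigma = 0.1, seed = 22))
  expect_false(identical(a$forearm$ax, c$forearm$ax))
  ses1 <- generate_session(2, throw_profile(noise_sigma = 0.05, seed = 5))
  ses2 <- generate_session(2, throw_profile(noise_sigma = 0.05, seed = 5))
  expect_identical(ses1$forearm, ses2$forearm)
})

test_that("generated counts respect the 16-bit range and profile validation works", {
  thr <- generate_throw(throw_profile(noise_sigma = 0.3, seed = 1))
  for (ch in c("forearm", "upperarm")) {
    m <- as.matrix(thr[[ch]][c("ax", "ay", "az")])
    expect_true(all(abs(m) <= 32768))
    expect_true(is.integer(m))
  }
  expect_error(throw_profile(step_durations = c(1, 1)), "step_durations")
  expect_error(throw_profile(noise_sigma = -1), "noise_sigma")
  expect_error(generate_error_throw(throw_profile(), "not-registered"),
               "unregistered")
})

test_that("clean end-to-end verdicts equal the ground truth for every profile", {
  profiles <- list(
    throw_profile(),
    throw_profile(step_durations = c(0.3, 0.4, 0.3, 0.3, 0.2, 0.3)),
    throw_profile(handedness = "left"))
  for (pr in profiles) {
    thr <- generate_throw(pr)
    res <- recognize_throw(pipeline_pair(thr))
    expect_identical(res$steps$ok, thr$truth$verdicts$ok)
  }
  for (id in registered_errors()$id) {
    thr <- generate_error_throw(throw_profile(), id)
    res <- recognize_throw(pipeline_pair(thr))
    expect_identical(res$steps$ok, thr$truth$verdicts$ok, label = id)
    expect_identical(res$steps$message[!res$steps$ok],
                     thr$truth$verdicts$message[!thr$truth$verdicts$ok],
                     label = id)
  }
})

test_that("per-sample symbol error rate is monotone in the noise level", {
  sigmas <- c(0, 0.05, 0.1, 0.2)
  rates <- vapply(seq_along(sigmas), function(i) {
    thr <- generate_throw(throw_profile(noise_sigma = sigmas[i], seed = 100 + i))
    pair <- pipeline_pair(thr)
    clean <- thr$truth$pair_sigma0$forearm
    got <- strsplit(pair$forearm, "")[[1]]
    want <- strsplit(clean, "")[[1]]
    mean(got != want)
  }, numeric(1))
  expect_equal(rates[1], 0)
  expect_true(all(diff(rates) >= 0))
})

test_that("moderate noise rarely perturbs the leveled symbols", {
  # targets at +/-0.6 vs thresholds at +/-0.35: a plateau flip needs a
  # 5-sigma excursion at sigma = 0.05, so away from class boundaries (where
  # threshold-crossing timing jitter, not amplitude noise, moves symbols by
  # a sample or two) the per-sample symbol error rate stays below 1%
  n_err <- 0L
  n_tot <- 0L
  for (s in 1:20) {
    thr <- generate_throw(throw_profile(noise_sigma = 0.05, seed = s))
    pair <- pipeline_pair(thr)
    got <- strsplit(pair$forearm, "")[[1]]
    want <- strsplit(thr$truth$pair_sigma0$forearm, "")[[1]]
    changed <- which(want[-1] != want[-length(want)])
    near_boundary <- unique(pmin(pmax(
      rep(changed, each = 11) + (-5:5), 1), length(want)))
    interior <- setdiff(seq_along(want), near_boundary)
    n_err <- n_err + sum(got[interior] != want[interior])
    n_tot <- n_tot + length(interior)
  }
  expect_lt(n_err / n_tot, 0.01)
})

test_that("sessions concatenate throws with recoverable boundaries", {
  ses <- generate_session(3, throw_profile(seed = 31))
  expect_equal(ses$truth$n_throws, 3)
  expect_equal(nrow(ses$truth$throw_bounds), 3)
  b <- ses$truth$throw_bounds
  expect_true(all(b$start < b$end))
  expect_true(all(diff(b$start) > 0))
  expect_lte(max(b$end), nrow(ses$forearm))
  # single-throw session reduces to rest + throw
  one <- generate_session(1, throw_profile(seed = 1))
  thr <- generate_throw(throw_profile(seed = 1))
  span <- one$truth$throw_bounds
  expect_equal(span$end - span$start + 1L, nrow(thr$forearm))
})
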