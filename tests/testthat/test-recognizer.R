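test_that("check_ready gates on a stable standing posture", {
  expect_true(check_ready(constant_levels("E", 60), constant_levels("e", 60))$ok)
  r <- check_ready(constant_levels("P", 60), constant_levels("e", 60))
  expect_false(r$ok)
  expect_identical(r$reason, "Worn too inside or outside")
  alternating <- do.call(rbind, rep(list(constant_levels("E", 5),
                                         constant_levels("P", 5)), 6))
  r2 <- check_ready(alternating, alternating)
  expect_false(r2$ok)
  expect_identical(r2$reason, "unstable")
  expect_error(check_ready(constant_levels("E", 10), constant_levels("e", 10),
                           min_hold = 50), "min_hold")
})

test_that("a clean throw passes all six phases with the display strings", {
  thr <- generate_throw(throw_profile(noise_sigma = 0))
  res <- recognize_throw(pipeline_pair(thr))
  expect_true(res$all_ok)
  expect_identical(res$steps$display, sprintf("S%d: OK!!", 1:6))
  expect_identical(res$steps$report, sprintf("STEP%d: OK!!", 1:6))
})

test_that("a throw with the step-4 forearm classes absent reports the elbow error", {
  thr <- generate_error_throw(throw_profile(), "elbow-not-high")
  res <- recognize_throw(pipeline_pair(thr))
  expect_false(res$steps$ok[4])
  expect_identical(res$steps$message[4], "Elbow is not high enough")
  expect_identical(res$steps$display[4], "S4: Elbow is not enough high!!")
  expect_identical(res$steps$report[4], "STEP4: Elbow is not high enough!!")
  expect_true(all(res$steps$ok[-4]))
})

test_that("each registered erroneous throw elicits exactly its message", {
  reg <- registered_errors()
  for (i in seq_len(nrow(reg))) {
    thr <- generate_error_throw(throw_profile(), reg$id[i])
    res <- recognize_throw(pipeline_pair(thr))
    expect_false(res$steps$ok[reg$step[i]], label = reg$id[i])
    expect_identical(res$steps$message[reg$step[i]], reg$message[i],
                     label = reg$id[i])
    expect_true(all(res$steps$ok[-reg$step[i]]), label = reg$id[i])
  }
})

test_that("a rest-only pair fails every phase", {
  n <- 100
  pair <- throw_seq_pair(paste(rep("1", n), collapse = ""),
                         paste(rep("2", n), collapse = ""))
  res <- recognize_throw(pair)
  expect_false(any(res$steps$ok))
  expect_error(recognize_throw(throw_seq_pair("", "")), "empty")
})

test_that("verdicts are invariant to throwing speed (run-length scaling)", {
  base <- c(0.6, 0.6, 0.5, 0.4, 0.3, 0.5)
  for (mult in 1:5) {
    thr <- generate_throw(throw_profile(step_durations = base * mult))
    res <- recognize_throw(pipeline_pair(thr))
    expect_true(res$all_ok, label = paste("speed x", mult))
  }
})

test_that("left-handed throws mirror to identical verdicts", {
  for (seed in 1:3) {
    thr_r <- generate_throw(throw_profile(handedness = "right", seed = seed))
    thr_l <- generate_throw(throw_profile(handedness = "left", seed = seed))
    res_r <- recognize_throw(pipeline_pair(thr_r))
    res_l <- recognize_throw(pipeline_pair(thr_l))
    expect_identical(res_l$steps$message, res_r$steps$message)
    expect_true(res_l$all_ok)
  }
})

test_that("process_stream segments a multi-throw session and is deterministic", {
  ses <- generate_session(3, throw_profile(seed = 11))
  rep1 <- process_stream(ses$forearm, ses$upperarm)
  expect_equal(rep1$n_throws, 3)
  expect_true(all(vapply(rep1$throws, `[[`, TRUE, "all_ok")))
  rep2 <- process_stream(ses$forearm, ses$upperarm)
  expect_identical(lapply(rep1$throws, `[[`, "steps"),
                   lapply(rep2$throws, `[[`, "steps"))
})

test_that("an interrupted throw is recorded incomplete, not misclassified", {
  ses <- generate_session(3, throw_profile(seed = 7),
                          error_ids = c(NA, "truncate:4", NA))
  rep <- process_stream(ses$forearm, ses$upperarm)
  expect_equal(rep$n_throws, 3)
  expect_true(rep$throws[[1]]$all_ok)
  expect_true(rep$throws[[3]]$all_ok)
  t2 <- rep$throws[[2]]
  expect_true(t2$incomplete)
  expect_identical(t2$steps$status[1:3], rep("ok", 3))
  expect_identical(t2$steps$status[4:6], rep("incomplete", 3))
})

test_that("no verdict is emitted when the readiness gate never passes", {
  # session whose idle periods are too short for the standing hold
  ses <- generate_session(1, throw_profile(seed = 2),
                          idle_gap = 0.1, lead_in = 0.1)
  rep <- process_stream(ses$forearm, ses$upperarm, min_hold = 50)
  expect_equal(rep$n_throws, 0)
})

test_that("aggregate_accuracy reproduces the printed evaluation aggregates", {
  agg <- aggregate_accuracy(evaluation_counts())
  expect_equal(unname(agg$per_user_avg), c(95.14, 91.42, 95.14))
  expect_equal(agg$overall, 93.90)
  expect_equal(unname(agg$per_step_avg[["0"]]), 99.33)
  expect_equal(min(agg$per_step_avg), 85.33)
  solo <- data.frame(user = 1, step = 0, k = 0, n = 50)
  expect_equal(aggregate_accuracy(solo)$cells$accuracy, 0)
  expect_error(aggregate_accuracy(data.frame(user = 1, step = 0, k = 0, n = 0)),
               "positive")
})

test_that("sub-template scores are diagnostic and flag matching windows", {
  thr <- generate_throw(throw_profile(noise_sigma = 0))
  sc <- score_subtemplates(pipeline_pair(thr))
  expect_equal(nrow(sc), 13)
  expect_true(all(sc$forearm >= 0 & sc$forearm <= 1))
  # the wind-up sub-template has full upper-arm support in a clean throw
  expect_gt(sc$forearm[sc$id == "Step 1"], 0)
})
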