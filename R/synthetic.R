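#' Synthetic throw profile
#'
#' Parameters of the two-channel signal generator. Step durations model the
#' user's throwing speed (slower throws produce longer symbol runs);
#' `target_level` is the plateau magnitude on the normalized scale, chosen
#' comfortably outside the +/-0.35 leveling band but inside +/-1;
#' `noise_sigma` is the standard deviation of additive Gaussian noise on the
#' normalized scale; `ramp_frac` is the fraction of each plateau spent
#' ramping linearly from the previous level.
#'
#' @param step_durations seconds per throwing phase, six positive values.
#' @param sample_rate sampling rate in Hz.
#' @param noise_sigma Gaussian noise SD, normalized scale (>= 0).
#' @param handedness `"right"` or `"left"`; left mirrors the x axis of both
#'   channels.
#' @param target_level plateau magnitude, normalized scale.
#' @param ramp_frac fraction of each plateau used for the entry ramp.
#' @param seed integer seed for reproducible noise, or `NULL`.
#' @return Object of class `throw_profile`.
#' @export
throw_profile <- function(step_durations = c(0.6, 0.6, 0.5, 0.4, 0.3, 0.5),
                          sample_rate = 100,
                          noise_sigma = 0,
                          handedness = c("right", "left"),
                          target_level = 0.6,
                          ramp_frac = 0.1,
                          seed = NULL) {
  handedness <- match.arg(handedness)
  stopifnot(length(step_durations) == 6, all(step_durations > 0),
            sample_rate > 0, noise_sigma >= 0,
            target_level > 0.35, target_level <= 1,
            ramp_frac >= 0, ramp_frac < 1)
  structure(list(step_durations = step_durations,
                 sample_rate = sample_rate,
                 noise_sigma = noise_sigma,
                 handedness = handedness,
                 target_level = target_level,
                 ramp_frac = ramp_frac,
                 seed = seed),
            class = "throw_profile")
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Per-channel plateau plan: one row per class plateau with its step index,
# class symbol, and sample count. Class run lengths split each step's
# duration as evenly as possible.
channel_plan <- function(profile, channel, db = builtin_db()) {
  rows <- list()
  for (k in 1:6) {
    tmpl <- db$phase_templates[[k]]
    classes <- if (channel == "forearm") tmpl$forearm_classes else tmpl$upper_classes
    n_step <- max(length(classes), round(profile$step_durations[k] * profile$sample_rate))
    lens <- even_allocation(n_step, length(classes))
    rows[[k]] <- data.frame(step = k, class = classes, n = lens,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# Piecewise-constant normalized signal with linear entry ramps.
signal_from_plan <- function(plan, profile, start_triple = NULL) {
  targets <- t(vapply(plan$class, function(s) symbol_to_triple(s)$triple,
                      numeric(3))) * profile$target_level
  n <- sum(plan$n)
  sig <- matrix(0, n, 3)
  prev <- if (is.null(start_triple)) targets[1, ] else start_triple
  pos <- 0L
  for (i in seq_len(nrow(plan))) {
    len <- plan$n[i]
    ramp <- min(len - 1L, floor(profile$ramp_frac * len))
    tgt <- targets[i, ]
    for (axis in 1:3) {
      vals <- rep(tgt[axis], len)
      if (ramp > 0) {
        vals[seq_len(ramp)] <- prev[axis] +
          (tgt[axis] - prev[axis]) * seq_len(ramp) / (ramp + 1)
      }
      sig[pos + seq_len(len), axis] <- vals
    }
    prev <- tgt
    pos <- pos + len
  }
  sig
}

normalized_to_counts <- function(sig) {
  counts <- round(sig * FULL_SCALE_COUNT)
  counts[counts > FULL_SCALE_COUNT] <- FULL_SCALE_COUNT
  counts[counts < -FULL_SCALE_COUNT] <- -FULL_SCALE_COUNT
  storage.mode(counts) <- "integer"
  counts
}

make_trace <- function(sig, profile, t0 = 0) {
  n <- nrow(sig)
  data.frame(t = t0 + (seq_len(n) - 1) / profile$sample_rate,
             ax = sig[, 1], ay = sig[, 2], az = sig[, 3])
}

# Core generator shared by correct and erroneous throws. `mutate_plan`
# rewrites the per-channel plateau plans to inject a deviant pattern.
generate_throw_impl <- function(profile, db, mutate_plan = NULL,
                                verdicts = NULL) {
  plan_f <- channel_plan(profile, "forearm", db)
  plan_u <- channel_plan(profile, "upperarm", db)
  # Upper plan stretched/cut to the forearm total per step so the channels
  # stay sample-aligned.
  for (k in 1:6) {
    nf <- sum(plan_f$n[plan_f$step == k])
    idx <- which(plan_u$step == k)
    plan_u$n[idx] <- even_allocation(nf, length(idx))
  }
  if (!is.null(mutate_plan)) {
    plans <- mutate_plan(plan_f, plan_u)
    plan_f <- plans$forearm
    plan_u <- plans$upperarm
  }
  sig_f <- signal_from_plan(plan_f, profile)
  sig_u <- signal_from_plan(plan_u, profile)
  if (profile$handedness == "left") {
    sig_f[, 1] <- -sig_f[, 1]
    sig_u[, 1] <- -sig_u[, 1]
  }
  clean_f <- normalized_to_counts(sig_f)
  clean_u <- normalized_to_counts(sig_u)
  n <- nrow(sig_f)
  noisy <- with_seed(profile$seed, {
    list(f = sig_f + matrix(rnorm(n * 3, 0, profile$noise_sigma), n, 3),
         u = sig_u + matrix(rnorm(n * 3, 0, profile$noise_sigma), n, 3))
  })
  trace_f <- make_trace(normalized_to_counts(noisy$f), profile)
  trace_u <- make_trace(normalized_to_counts(noisy$u), profile)

  cfg <- sensor_config(mode = profile$handedness)
  pair_sigma0 <- encode_pair(
    preprocess_trace(make_trace(clean_f, profile), cfg),
    preprocess_trace(make_trace(clean_u, profile), cfg))
  ends <- cumsum(tapply(plan_f$n, plan_f$step, sum))
  bounds <- data.frame(step = 1:6,
                       start = c(1L, head(ends, -1) + 1L),
                       end = as.integer(ends))
  if (is.null(verdicts))
    verdicts <- data.frame(step = 1:6, ok = TRUE, message = "OK!!",
                           stringsAsFactors = FALSE)
  truth <- list(
    intended_forearm = rep(plan_f$class, plan_f$n),
    intended_upperarm = rep(plan_u$class, plan_u$n),
    step_bounds = bounds,
    pair_sigma0 = pair_sigma0,
    verdicts = verdicts)
  list(forearm = trace_f, upperarm = trace_u, truth = truth,
       profile = profile)
}

#' Generate one correct synthetic throw
#'
#' Emits two sample-aligned raw traces (forearm and upper arm) realizing the
#' six-phase template class sequences as piecewise-constant normalized
#' plateaus at `+/-target_level` (or 0), with linear entry ramps, optional
#' additive Gaussian noise, and conversion to clipped integer counts. The
#' ground truth carries the intended per-sample classes, per-step sample
#' boundaries, the noiseless pipeline symbols, and the intended verdicts.
#'
#' @param profile a [throw_profile()].
#' @param db a `template_db`.
#' @return List with `forearm`, `upperarm` (raw traces), `truth`, `profile`.
#' @export
generate_throw <- function(profile = throw_profile(), db = builtin_db()) {
  generate_throw_impl(profile, db)
}

# Forearm/upper-arm substitute symbols for generic wrong-action errors:
# the (1,-1,-1) triple is unused by every template.
WRONG_ACTION <- c(forearm = "W", upperarm = "w")

#' Registered erroneous-throw generators
#'
#' @return Data frame with the generator `id`, the `step` it corrupts, and
#'   the erroneous-action `message` the recognizer is expected to report.
#' @export
registered_errors <- function() {
  data.frame(
    id = c(paste0("error-", 1:6), "elbow-not-high", "no-follow-through"),
    step = c(1:6, 4L, 6L),
    message = c(paste0("Error-", 1:6), "Elbow is not high enough",
                "No follow-through"),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic throw with a registered erroneous action
#'
#' As [generate_throw()], but the targeted step's class pattern is replaced
#' by its registered deviant: `error-k` substitutes an off-template posture
#' on both channels during step k; `elbow-not-high` silences the forearm
#' during Step 4 while the upper arm proceeds; `no-follow-through` replaces
#' Step 6 with rest on both channels. The ground-truth verdicts mark the
#' corrupted step failed with its expected message.
#'
#' @param profile a [throw_profile()].
#' @param error_id one of [registered_errors()]`$id`.
#' @param db a `template_db`.
#' @return As [generate_throw()].
#' @export
generate_error_throw <- function(profile = throw_profile(), error_id,
                                 db = builtin_db()) {
  reg <- registered_errors()
  if (!error_id %in% reg$id)
    stop("unregistered error id: '", error_id, "'")
  row <- reg[reg$id == error_id, ]
  k <- row$step
  mutate <- function(plan_f, plan_u) {
    collapse_step <- function(plan, sym) {
      idx <- which(plan$step == k)
      total <- sum(plan$n[idx])
      keep <- plan[plan$step != k, ]
      repl <- data.frame(step = k, class = sym, n = total,
                         stringsAsFactors = FALSE)
      out <- rbind(keep[keep$step < k, ], repl, keep[keep$step > k, ])
      rownames(out) <- NULL
      out
    }
    if (grepl("^error-", error_id)) {
      plan_f <- collapse_step(plan_f, WRONG_ACTION[["forearm"]])
      plan_u <- collapse_step(plan_u, WRONG_ACTION[["upperarm"]])
    } else if (error_id == "elbow-not-high") {
      plan_f <- collapse_step(plan_f, REST_SYMBOLS[["forearm"]])
    } else if (error_id == "no-follow-through") {
      plan_f <- collapse_step(plan_f, REST_SYMBOLS[["forearm"]])
      plan_u <- collapse_step(plan_u, REST_SYMBOLS[["upperarm"]])
    }
    list(forearm = plan_f, upperarm = plan_u)
  }
  verdicts <- data.frame(step = 1:6, ok = TRUE, message = "OK!!",
                         stringsAsFactors = FALSE)
  verdicts$ok[k] <- FALSE
  verdicts$message[k] <- row$message
  generate_throw_impl(profile, db, mutate_plan = mutate, verdicts = verdicts)
}

#' Generate a multi-throw session with idle gaps
#'
#' Concatenates standing-rest segments (long enough for the Step 0 gate)
#' with complete or truncated throws, recording each throw's sample
#' boundaries in the ground truth.
#'
#' @param n_throws number of throws (>= 1).
#' @param profiles a single [throw_profile()] reused for every throw, or a
#'   list of one profile per throw.
#' @param idle_gap standing time between throws, seconds.
#' @param lead_in standing time before the first throw, seconds.
#' @param error_ids optional character vector, one per throw: `NA` for a
#'   correct throw, a [registered_errors()] id for an erroneous one, or
#'   `"truncate:<k>"` to cut the throw off before step k begins.
#' @param db a `template_db`.
#' @return List with `forearm`, `upperarm` (session traces), `truth`
#'   (per-throw truths and `throw_bounds`).
#' @export
generate_session <- function(n_throws = 1, profiles = throw_profile(),
                             idle_gap = 1.0, lead_in = 1.0,
                             error_ids = NULL, db = builtin_db()) {
  stopifnot(n_throws >= 1)
  if (inherits(profiles, "throw_profile"))
    profiles <- rep(list(profiles), n_throws)
  stopifnot(length(profiles) == n_throws)
  if (is.null(error_ids)) error_ids <- rep(NA_character_, n_throws)

  standing_block <- function(profile, seconds) {
    n <- max(1L, round(seconds * profile$sample_rate))
    triple <- symbol_to_triple(db$standing[["forearm"]])$triple *
      profile$target_level
    sig <- matrix(rep(triple, each = n), n, 3)
    sig_u <- matrix(rep(symbol_to_triple(db$standing[["upperarm"]])$triple *
                          profile$target_level, each = n), n, 3)
    if (profile$handedness == "left") {
      sig[, 1] <- -sig[, 1]
      sig_u[, 1] <- -sig_u[, 1]
    }
    noise_sd <- profile$noise_sigma
    if (noise_sd > 0) {
      sig <- sig + matrix(rnorm(n * 3, 0, noise_sd), n, 3)
      sig_u <- sig_u + matrix(rnorm(n * 3, 0, noise_sd), n, 3)
    }
    list(f = normalized_to_counts(sig), u = normalized_to_counts(sig_u))
  }

  seg_f <- list(); seg_u <- list()
  throw_truths <- list()
  bounds <- data.frame(throw = integer(0), start = integer(0), end = integer(0))
  total <- 0L
  base_seed <- profiles[[1]]$seed
  run <- function() {
    for (i in seq_len(n_throws)) {
      pr <- profiles[[i]]
      pr$seed <- NULL  # session-level seeding governs all noise
      gap <- if (i == 1) lead_in else idle_gap
      blk <- standing_block(pr, gap)
      seg_f[[length(seg_f) + 1L]] <<- blk$f
      seg_u[[length(seg_u) + 1L]] <<- blk$u
      total <<- total + nrow(blk$f)
      eid <- error_ids[i]
      thr <- if (is.na(eid)) {
        generate_throw(pr, db)
      } else if (grepl("^truncate:", eid)) {
        cut_step <- as.integer(sub("^truncate:", "", eid))
        full <- generate_throw(pr, db)
        cut_at <- full$truth$step_bounds$start[full$truth$step_bounds$step == cut_step]
        full$forearm <- full$forearm[seq_len(cut_at - 1L), ]
        full$upperarm <- full$upperarm[seq_len(cut_at - 1L), ]
        full$truth$truncated_at <- cut_step
        full
      } else {
        generate_error_throw(pr, eid, db)
      }
      nf <- nrow(thr$forearm)
      seg_f[[length(seg_f) + 1L]] <<- as.matrix(thr$forearm[c("ax", "ay", "az")])
      seg_u[[length(seg_u) + 1L]] <<- as.matrix(thr$upperarm[c("ax", "ay", "az")])
      bounds <<- rbind(bounds, data.frame(throw = i, start = total + 1L,
                                          end = total + nf))
      total <<- total + nf
      throw_truths[[i]] <<- thr$truth
    }
    # trailing idle so the last throw closes cleanly
    blk <- standing_block(profiles[[n_throws]], idle_gap)
    seg_f[[length(seg_f) + 1L]] <<- blk$f
    seg_u[[length(seg_u) + 1L]] <<- blk$u
    total <<- total + nrow(blk$f)
  }
  with_seed(base_seed, run())

  rate <- profiles[[1]]$sample_rate
  f_all <- do.call(rbind, seg_f)
  u_all <- do.call(rbind, seg_u)
  t <- (seq_len(total) - 1) / rate
  list(forearm = data.frame(t = t, ax = f_all[, 1], ay = f_all[, 2], az = f_all[, 3]),
       upperarm = data.frame(t = t, ax = u_all[, 1], ay = u_all[, 2], az = u_all[, 3]),
       truth = list(throws = throw_truths, throw_bounds = bounds,
                    n_throws = n_throws))
}
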