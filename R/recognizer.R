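REST_SYMBOLS <- c(forearm = "1", upperarm = "2")

# Run view of a symbol string with sample positions.
symbol_runs <- function(seq) {
  r <- compress_runs(seq)
  ends <- cumsum(r$lengths)
  data.frame(symbol = r$symbols,
             start = ends - r$lengths + 1L,
             end = ends,
             stringsAsFactors = FALSE)
}

# Greedy in-order search for a chain of class runs at or after `from`.
# Each class is taken at its first qualifying run; returns c(start, end)
# sample window or NULL when the chain cannot be completed.
find_class_chain <- function(runs, classes, from) {
  i <- 1L
  k <- 1L
  start <- NA_integer_
  end <- NA_integer_
  n_runs <- nrow(runs)
  while (i <= n_runs && k <= length(classes)) {
    if (runs$end[i] >= from && runs$symbol[i] == classes[k]) {
      if (k == 1L) start <- max(runs$start[i], from)
      end <- runs$end[i]
      k <- k + 1L
    }
    i <- i + 1L
  }
  if (k > length(classes)) c(start, end) else NULL
}

#' Action balance judgment for the getting-ready status (Step 0)
#'
#' Verifies, before recognition starts, that the device is worn correctly and
#' the user is standing still: both channels must hold a constant leveled
#' triple for at least `min_hold` consecutive samples, and that triple must
#' be the standing-posture class of its channel (gravity along -y with the
#' arms hanging: forearm `E`, upper arm `e`).
#'
#' @param forearm_levels,upper_levels leveled traces (columns `lx, ly, lz`)
#'   covering at least `min_hold` samples.
#' @param min_hold required stable run length, in samples.
#' @param db a `template_db` (supplies the standing classes).
#' @return List with `ok` (logical) and `reason` (`"ready"`,
#'   `"Worn too inside or outside"`, or `"unstable"`).
#' @export
check_ready <- function(forearm_levels, upper_levels, min_hold = 50,
                        db = builtin_db()) {
  if (nrow(forearm_levels) < min_hold || nrow(upper_levels) < min_hold)
    stop("window must cover at least `min_hold` samples per channel")
  lev_cols <- c("lx", "ly", "lz")
  fore <- triple_to_symbol(as.matrix(forearm_levels[lev_cols]), "forearm")
  upper <- triple_to_symbol(as.matrix(upper_levels[lev_cols]), "upperarm")
  stable_symbol <- function(symbols) {
    r <- rle(symbols)
    idx <- which(r$lengths >= min_hold)
    if (length(idx) == 0L) return(NA_character_)
    r$values[idx[length(idx)]]  # most recent stable run
  }
  s_fore <- stable_symbol(fore)
  s_upper <- stable_symbol(upper)
  if (is.na(s_fore) || is.na(s_upper))
    return(list(ok = FALSE, reason = "unstable"))
  if (s_fore == db$standing[["forearm"]] && s_upper == db$standing[["upperarm"]])
    return(list(ok = TRUE, reason = "ready"))
  list(ok = FALSE, reason = "Worn too inside or outside")
}

#' Recognize one throw against the template database
#'
#' Scans the two-channel symbol pair left to right. For each numbered phase
#' (Steps 1-6) the forearm class chain is located greedily after the current
#' cursor and the delimited window must satisfy [match_step()] on both
#' channels simultaneously; a passing step advances the cursor past its
#' window. A failing step receives an erroneous-action message: a registered
#' deviant pattern's message when one matches (e.g. "Elbow is not high
#' enough" when the Step 4 forearm classes are absent while the upper arm
#' proceeds), "No follow-through" when the Step 6 region holds only
#' rest/standing symbols, otherwise the step's generic `Error-k`. A throw
#' whose remaining signal is pure rest/standing before Step 6 is reached is
#' marked incomplete rather than misclassified.
#'
#' @param pair a [throw_seq_pair()] covering one throw (readiness already
#'   gated by [check_ready()]).
#' @param db a `template_db`; default [builtin_db()].
#' @param theta LCS similarity threshold, default 0.7.
#' @param rest_slack non-idle samples tolerated in a suffix still considered
#'   "at rest": posture transitions sweep through intermediate symbols for a
#'   few samples (filter lag), which must not disguise an abandoned throw as
#'   an erroneous action.
#' @return Object of class `throw_result`: data frame `steps` with columns
#'   `step, ok, status, message, display, report`, plus `incomplete` and
#'   `all_ok` flags.
#' @export
recognize_throw <- function(pair, db = builtin_db(), theta = 0.7,
                            rest_slack = 10L) {
  if (nchar(pair$forearm) == 0L) stop("empty sequence pair")
  n <- nchar(pair$forearm)
  fore_chars <- strsplit(pair$forearm, "")[[1]]
  upper_chars <- strsplit(pair$upperarm, "")[[1]]
  runs_fore <- symbol_runs(pair$forearm)
  runs_upper <- symbol_runs(pair$upperarm)
  idle_fore <- c(REST_SYMBOLS[["forearm"]], db$standing[["forearm"]])
  idle_upper <- c(REST_SYMBOLS[["upperarm"]], db$standing[["upperarm"]])

  steps <- data.frame(step = 1:6, ok = FALSE, status = "error",
                      message = "", stringsAsFactors = FALSE)
  display_text <- character(6)
  cursor <- 1L
  interrupted <- FALSE

  for (k in 1:6) {
    if (interrupted) {
      steps$status[k] <- "incomplete"
      steps$message[k] <- "incomplete"
      display_text[k] <- "incomplete"
      next
    }
    tmpl <- db$phase_templates[[k]]
    win <- find_class_chain(runs_fore, tmpl$forearm_classes, cursor)
    ok <- FALSE
    if (!is.null(win)) {
      seg <- throw_seq_pair(substr(pair$forearm, win[1], win[2]),
                            substr(pair$upperarm, win[1], win[2]))
      ok <- isTRUE(c(match_step(seg, tmpl, theta)))
    }
    if (ok) {
      steps$ok[k] <- TRUE
      steps$status[k] <- "ok"
      steps$message[k] <- "OK!!"
      display_text[k] <- "OK!!"
      cursor <- win[2] + 1L
      next
    }
    # Failed: classify.
    rest_tail <- if (cursor > n) TRUE else {
      active <- !(fore_chars[cursor:n] %in% idle_fore) |
        !(upper_chars[cursor:n] %in% idle_upper)
      sum(active) <= rest_slack
    }
    cls <- classify_step_error(k, tmpl, db, runs_fore, runs_upper,
                               fore_chars, upper_chars, cursor, n, rest_tail)
    if (identical(cls$status, "incomplete")) {
      interrupted <- TRUE
      steps$status[k] <- "incomplete"
      steps$message[k] <- "incomplete"
      display_text[k] <- "incomplete"
    } else {
      steps$status[k] <- "error"
      steps$message[k] <- cls$message
      display_text[k] <- cls$display
      if (!is.na(cls$advance)) cursor <- cls$advance
    }
  }

  steps$display <- ifelse(steps$status == "incomplete",
                          sprintf("S%d: incomplete", steps$step),
                          sprintf("S%d: %s", steps$step,
                                  ifelse(steps$ok, "OK!!",
                                         paste0(display_text, "!!"))))
  steps$report <- ifelse(steps$status == "incomplete",
                         sprintf("STEP%d: incomplete", steps$step),
                         sprintf("STEP%d: %s", steps$step,
                                 ifelse(steps$ok, "OK!!",
                                        paste0(steps$message, "!!"))))
  structure(list(steps = steps,
                 incomplete = any(steps$status == "incomplete"),
                 all_ok = all(steps$ok),
                 theta = theta),
            class = "throw_result")
}

# Decide the message for a failed step k. Registered deviant patterns are
# tried first, then the interrupt rule, then the generic Error-k.
classify_step_error <- function(k, tmpl, db, runs_fore, runs_upper,
                                fore_chars, upper_chars, cursor, n, rest_tail) {
  for (pat in db$error_patterns) {
    if (pat$step != k) next
    if (pat$rule == "forearm_absent_upper_ok") {
      win_u <- find_class_chain(runs_upper, tmpl$upper_classes, cursor)
      if (!is.null(win_u)) {
        span <- fore_chars[win_u[1]:win_u[2]]
        if (!any(span %in% tmpl$forearm_classes)) {
          return(list(status = "error", message = pat$message,
                      display = pat$display, advance = win_u[2] + 1L))
        }
      }
    } else if (pat$rule == "all_rest") {
      if (rest_tail)
        return(list(status = "error", message = pat$message,
                    display = pat$display, advance = NA_integer_))
    }
  }
  if (rest_tail)
    return(list(status = "incomplete", message = "incomplete",
                display = "incomplete", advance = NA_integer_))
  generic <- sprintf("Error-%d", k)
  list(status = "error", message = generic, display = generic,
       advance = NA_integer_)
}

#' @export
print.throw_result <- function(x, ...) {
  cat("<throw_result>",
      if (x$all_ok) "all steps OK" else if (x$incomplete) "incomplete"
      else "errors detected", "\n")
  cat(paste0("  ", x$steps$display, collapse = "\n"), "\n")
  invisible(x)
}

#' Process a continuous two-channel stream into per-throw verdicts
#'
#' Repeatedly: (a) waits for the getting-ready gate ([check_ready()]) to
#' pass on a sustained standing posture, (b) detects motion onset as either
#' channel leaving its standing class for at least `onset_hold` consecutive
#' samples, (c) delimits the throw at the next sustained idle
#' (standing/rest) run of `close_hold` samples or at stream end, and
#' (d) recognizes the delimited throw. A stream that ends mid-throw yields
#' an incomplete `throw_result`, and no verdict is ever emitted for a stream
#' whose readiness gate never passes.
#'
#' @param forearm_raw,upper_raw raw traces (columns `t, ax, ay, az`).
#' @param config a [sensor_config()].
#' @param db a `template_db`.
#' @param theta LCS similarity threshold.
#' @param min_hold samples the standing posture must hold for Step 0.
#' @param onset_hold consecutive non-standing samples that trigger onset.
#' @param close_hold consecutive idle samples that close a throw window.
#' @return Object of class `session_report`: list of `throw_result`s plus
#'   the sample windows and settings used.
#' @export
process_stream <- function(forearm_raw, upper_raw,
                           config = sensor_config(), db = builtin_db(),
                           theta = 0.7, min_hold = 50, onset_hold = 3,
                           close_hold = 30) {
  lev_f <- preprocess_trace(forearm_raw, config)
  lev_u <- preprocess_trace(upper_raw, config)
  n <- nrow(lev_f)
  fore <- triple_to_symbol(as.matrix(lev_f[c("lx", "ly", "lz")]), "forearm")
  upper <- triple_to_symbol(as.matrix(lev_u[c("lx", "ly", "lz")]), "upperarm")
  standing <- fore == db$standing[["forearm"]] & upper == db$standing[["upperarm"]]
  idle <- (fore %in% c(db$standing[["forearm"]], REST_SYMBOLS[["forearm"]])) &
    (upper %in% c(db$standing[["upperarm"]], REST_SYMBOLS[["upperarm"]]))

  run_end_of <- function(flag, from, hold) {
    # first index >= from at which `flag` has held for `hold` samples
    run <- 0L
    for (i in from:n) {
      run <- if (flag[i]) run + 1L else 0L
      if (run >= hold) return(i)
    }
    NA_integer_
  }

  throws <- list()
  windows <- data.frame(onset = integer(0), end = integer(0))
  i <- 1L
  while (i <= n) {
    ready_at <- run_end_of(standing, i, min_hold)
    if (is.na(ready_at)) break
    onset_at <- run_end_of(!standing, ready_at + 1L, onset_hold)
    if (is.na(onset_at)) break
    onset <- onset_at - onset_hold + 1L
    close_at <- run_end_of(idle, onset_at, close_hold)
    end <- if (is.na(close_at)) n else close_at - close_hold
    pair <- throw_seq_pair(paste(fore[onset:end], collapse = ""),
                           paste(upper[onset:end], collapse = ""))
    throws[[length(throws) + 1L]] <- recognize_throw(pair, db, theta)
    windows <- rbind(windows, data.frame(onset = onset, end = end))
    if (is.na(close_at)) break
    i <- close_at - close_hold + 1L
  }
  structure(list(throws = throws, windows = windows, n_throws = length(throws),
                 theta = theta, mode = config$mode),
            class = "session_report")
}

#' @export
print.session_report <- function(x, ...) {
  cat(sprintf("<session_report> %d throw(s), theta=%g, mode=%s\n",
              x$n_throws, x$theta, x$mode))
  for (i in seq_along(x$throws)) {
    r <- x$throws[[i]]
    status <- if (r$all_ok) "all OK" else if (r$incomplete) "incomplete"
              else paste(r$steps$message[!r$steps$ok & r$steps$status == "error"],
                         collapse = "; ")
    cat(sprintf("  throw %d: %s\n", i, status))
  }
  invisible(x)
}

# Truncate toward zero at `digits` decimals (reproduces printed aggregates
# such as 640/7 -> 91.42).
trunc_toward_zero <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 1e-9) / scale
}

#' Aggregate per-step identification counts into accuracy percentages
#'
#' Computes the identification rate 100 k/n for every (user, step) cell,
#' per-user averages over the seven stages (Steps 0-6), per-step cross-user
#' averages, and the overall mean of the per-user averages. Reported values
#' are truncated toward zero at two decimals (so 640/7 reports as 91.42).
#'
#' @param counts data frame with columns `user`, `step` (0-6), `k`
#'   (correctly identified), `n` (attempts, > 0).
#' @return Object of class `accuracy_report`: `cells` (the input with an
#'   `accuracy` column), `per_user_avg`, `per_step_avg`, `overall`.
#' @export
aggregate_accuracy <- function(counts) {
  req <- c("user", "step", "k", "n")
  if (!all(req %in% names(counts)))
    stop("`counts` needs columns user, step, k, n")
  if (any(counts$n <= 0)) stop("`n` must be positive for every cell")
  acc <- 100 * counts$k / counts$n
  cells <- counts
  cells$accuracy <- trunc_toward_zero(acc)
  per_user <- c(tapply(acc, counts$user, mean))  # drop 1-d array shape
  per_step <- c(tapply(acc, counts$step, mean))
  overall <- mean(per_user)
  structure(list(cells = cells,
                 per_user_avg = trunc_toward_zero(per_user),
                 per_step_avg = trunc_toward_zero(per_step),
                 overall = trunc_toward_zero(overall)),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat("<accuracy_report>\n")
  users <- names(x$per_user_avg)
  steps <- sort(unique(x$cells$step))
  header <- sprintf("%-8s", "Stage")
  for (u in users) header <- paste0(header, sprintf("%16s", paste("User", u)))
  cat(header, "\n")
  for (s in steps) {
    row <- sprintf("Step %-3s", s)
    for (u in users) {
      cell <- x$cells[x$cells$step == s & x$cells$user == u, ]
      row <- paste0(row, sprintf("%8s %6.2f",
                                 paste0(cell$k[1], "/", cell$n[1]),
                                 cell$accuracy[1]))
    }
    cat(row, "\n")
  }
  cat(sprintf("%-8s", "Average"))
  for (u in users) cat(sprintf("%15.2f ", x$per_user_avg[[u]]))
  cat("\n")
  cat(sprintf("Overall: %.2f\n", x$overall))
  invisible(x)
}

#' Score a throw against the ordered sub-templates
#'
#' Advisory continuity diagnostics: each of the 13 sub-step/transition
#' templates is scored by its best LCS similarity over the whole pair; the
#' verdict logic in [recognize_throw()] does not gate on these.
#'
#' @param pair a [throw_seq_pair()].
#' @param db a `template_db`.
#' @param theta threshold used only to flag which sub-templates pass.
#' @return Data frame with `id`, per-channel ratios and a `pass` flag.
#' @export
score_subtemplates <- function(pair, db = builtin_db(), theta = 0.7) {
  res <- lapply(db$sub_templates, function(tmpl) {
    m <- match_step(pair, tmpl, theta)
    sc <- attr(m, "scores")
    data.frame(id = tmpl$id, forearm = sc[["forearm"]],
               upperarm = sc[["upperarm"]], pass = c(m),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
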