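#' Read a two-channel raw trace
#'
#' Two dialects: a pair of per-channel CSV files with header `t,ax,ay,az`,
#' or a single CSV with an additional `channel` column holding `forearm` /
#' `upperarm`. Counts must be integers in \eqn{[-32768, 32768]} and `t`
#' monotone non-decreasing; violations raise errors naming the offending
#' column and row.
#'
#' @param path path to the forearm CSV (pair dialect) or the combined CSV.
#' @param upper_path path to the upper-arm CSV, or `NULL` for the
#'   single-file dialect.
#' @return List with `forearm` and `upperarm` trace data frames.
#' @export
read_trace <- function(path, upper_path = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (!is.null(upper_path)) {
    fore <- read.csv(path)
    upper <- read.csv(upper_path)
  } else {
    combined <- read.csv(path)
    if (!"channel" %in% names(combined))
      stop("single-file dialect requires a `channel` column")
    fore <- combined[combined$channel == "forearm",
                     setdiff(names(combined), "channel")]
    upper <- combined[combined$channel == "upperarm",
                      setdiff(names(combined), "channel")]
    rownames(fore) <- rownames(upper) <- NULL
  }
  if (nrow(fore) == 0L) stop("missing channel: forearm")
  if (nrow(upper) == 0L) stop("missing channel: upperarm")
  validate_raw_trace(fore)
  validate_raw_trace(upper)
  list(forearm = fore, upperarm = upper)
}

#' Write a two-channel raw trace
#'
#' @param traces list with `forearm` and `upperarm` data frames.
#' @param path output CSV (single-file dialect unless `upper_path` given).
#' @param upper_path optional second CSV for the pair dialect.
#' @export
write_trace <- function(traces, path, upper_path = NULL) {
  cols <- c("t", "ax", "ay", "az")
  if (!is.null(upper_path)) {
    write.csv(traces$forearm[cols], path, row.names = FALSE)
    write.csv(traces$upperarm[cols], upper_path, row.names = FALSE)
  } else {
    fore <- traces$forearm[cols]
    fore$channel <- "forearm"
    upper <- traces$upperarm[cols]
    upper$channel <- "upperarm"
    write.csv(rbind(fore, upper), path, row.names = FALSE)
  }
  invisible(path)
}

PIPELINE_KEYS <- c("forearm", "upperarm", "input",
                   "sensitivity_forearm", "sensitivity_upperarm",
                   "full_scale_g", "level_threshold", "kalman_q", "kalman_r",
                   "mode", "theta", "min_hold", "onset_hold", "close_hold",
                   "template_db", "seed")

#' Read a pipeline configuration file
#'
#' YAML (`.yml` / `.yaml`) or JSON. Keys mirror [sensor_config()] field names
#' plus `forearm` / `upperarm` (or `input`) trace paths, `theta`, `mode`,
#' the stream-segmentation holds, an optional `template_db` path, and an
#' optional `seed`. Unknown keys are rejected by name.
#'
#' @param path configuration file.
#' @return Named list of settings.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required for YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  validate_config(cfg)
}

#' @rdname read_config
#' @param cfg a named list of settings to validate.
#' @export
validate_config <- function(cfg) {
  unknown <- setdiff(names(cfg), PIPELINE_KEYS)
  if (length(unknown) > 0)
    stop("unknown config key: '", unknown[1], "'")
  cfg
}

#' Run the full recognition pipeline from a configuration
#'
#' Read, preprocess, encode, recognize, report: loads the traces named in
#' the config, builds the [sensor_config()], and runs [process_stream()].
#'
#' @param config named list as from [read_config()], or a path to a config
#'   file.
#' @return A `session_report`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  config <- validate_config(config)
  traces <- if (!is.null(config$input)) {
    read_trace(config$input)
  } else if (!is.null(config$forearm)) {
    read_trace(config$forearm, config$upperarm)
  } else {
    stop("config must name input traces (`input` or `forearm`/`upperarm`)")
  }
  take <- function(key, default) if (is.null(config[[key]])) default else config[[key]]
  scfg <- sensor_config(
    sensitivity_forearm = take("sensitivity_forearm", 2048),
    sensitivity_upperarm = take("sensitivity_upperarm", 4096),
    full_scale_g = take("full_scale_g", 16),
    level_threshold = take("level_threshold", 0.35),
    kalman_q = take("kalman_q", 0.01),
    kalman_r = take("kalman_r", 0.1),
    mode = take("mode", "right"))
  db <- if (is.null(config$template_db)) builtin_db() else load_db(config$template_db)
  process_stream(traces$forearm, traces$upperarm,
                 config = scfg, db = db,
                 theta = take("theta", 0.7),
                 min_hold = take("min_hold", 50),
                 onset_hold = take("onset_hold", 3),
                 close_hold = take("close_hold", 30))
}

#' Serialize a session report
#'
#' @param report a `session_report`.
#' @param path output file.
#' @param format `"json"` (machine-readable, deterministic for identical
#'   inputs) or `"text"` (the per-throw display lines).
#' @export
write_report <- function(report, path, format = c("json", "text")) {
  format <- match.arg(format)
  if (format == "json") {
    ser <- list(
      n_throws = report$n_throws,
      theta = report$theta,
      mode = report$mode,
      windows = report$windows,
      throws = lapply(report$throws, function(r)
        list(all_ok = r$all_ok, incomplete = r$incomplete, steps = r$steps)))
    jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  } else {
    lines <- c(sprintf("throws: %d  theta: %g  mode: %s",
                       report$n_throws, report$theta, report$mode))
    for (i in seq_along(report$throws)) {
      lines <- c(lines, sprintf("-- throw %d --", i),
                 report$throws[[i]]$steps$display)
    }
    writeLines(lines, path)
  }
  invisible(path)
}

#' Tabulate verdicts of a synthetic session against its ground truth
#'
#' Builds an identification-count table in the shape consumed by
#' [aggregate_accuracy()]: Step 0 counts readiness gatings (one per intended
#' throw), Steps 1-6 count throws whose verdict for that step matches the
#' ground-truth verdict (OK for a correct step, the registered message for a
#' corrupted one).
#'
#' @param report a `session_report` from [process_stream()].
#' @param truth the `truth` element of [generate_session()].
#' @param user user label for the output rows.
#' @return Data frame with columns `user, step, k, n`.
#' @export
evaluate_session <- function(report, truth, user = 1) {
  n <- truth$n_throws
  k <- integer(7)  # steps 0..6
  k[1] <- min(report$n_throws, n)  # a recognized throw implies Step 0 passed
  for (i in seq_len(min(report$n_throws, n))) {
    got <- report$throws[[i]]$steps
    want <- truth$throws[[i]]$verdicts
    for (s in 1:6) {
      ok_match <- if (want$ok[s]) got$ok[s]
                  else (!got$ok[s] && got$message[s] == want$message[s])
      if (isTRUE(ok_match)) k[s + 1] <- k[s + 1] + 1L
    }
  }
  data.frame(user = user, step = 0:6, k = k, n = n)
}
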