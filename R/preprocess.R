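#' Sensor and pipeline configuration
#'
#' Bundles the constants of the acquisition hardware and the preprocessing
#' stage. The accelerometers report signed 16-bit counts in
#' \eqn{[-32768, +32768]}; sensitivities are 2048 LSB/g (forearm) and
#' 4096 LSB/g (upper arm) at a +/-16 g full scale. Leveling uses a symmetric
#' band: normalized values above `+level_threshold` map to +1, below
#' `-level_threshold` to -1, and to 0 otherwise.
#'
#' `kalman_q` and `kalman_r` are the process- and measurement-noise variances
#' of the scalar constant-state Kalman filter, expressed on the normalized
#' (fraction-of-full-scale) scale; [preprocess_trace()] rescales them by
#' \eqn{32768^2} when filtering raw counts, which is equivalent because the
#' Kalman recursion is scale-equivariant.
#'
#' @param sensitivity_forearm counts per g for the forearm sensor.
#' @param sensitivity_upperarm counts per g for the upper-arm sensor.
#' @param full_scale_g measurement range in g.
#' @param level_threshold symmetric leveling band half-width (dimensionless).
#' @param kalman_q process-noise variance (normalized scale).
#' @param kalman_r measurement-noise variance (normalized scale).
#' @param mode `"right"` or `"left"` handedness. Left-hand mode mirrors the
#'   throw by inverting the x axis of both channels before leveling.
#' @return An object of class `sensor_config`.
#' @export
sensor_config <- function(sensitivity_forearm = 2048,
                          sensitivity_upperarm = 4096,
                          full_scale_g = 16,
                          level_threshold = 0.35,
                          kalman_q = 0.01,
                          kalman_r = 0.1,
                          mode = c("right", "left")) {
  mode <- match.arg(mode)
  stopifnot(sensitivity_forearm > 0, sensitivity_upperarm > 0,
            full_scale_g > 0,
            level_threshold > 0, level_threshold < 1,
            kalman_q > 0, kalman_r > 0)
  structure(
    list(sensitivity_forearm = sensitivity_forearm,
         sensitivity_upperarm = sensitivity_upperarm,
         full_scale_g = full_scale_g,
         level_threshold = level_threshold,
         kalman_q = kalman_q,
         kalman_r = kalman_r,
         mode = mode),
    class = "sensor_config")
}

#' @export
print.sensor_config <- function(x, ...) {
  cat("<sensor_config>\n")
  cat(sprintf("  sensitivity: forearm %g, upper arm %g counts/g (+/-%g g)\n",
              x$sensitivity_forearm, x$sensitivity_upperarm, x$full_scale_g))
  cat(sprintf("  leveling band: +/-%g   kalman: q=%g r=%g   mode: %s\n",
              x$level_threshold, x$kalman_q, x$kalman_r, x$mode))
  invisible(x)
}

#' Scalar constant-state Kalman filter
#'
#' Filters an ordered series of scalar measurements under a random-walk
#' (constant-state) model. Predict: \eqn{x^- = x}, \eqn{p^- = p + q}.
#' Update: \eqn{k = p^-/(p^- + r)}, \eqn{x = x^- + k (z - x^-)},
#' \eqn{p = (1 - k) p^-}. Applied independently to each of the six axis
#' channels by [preprocess_trace()].
#'
#' @param series numeric vector of measurements, in time order.
#' @param q process-noise variance (> 0).
#' @param r measurement-noise variance (> 0).
#' @param x0 initial state estimate; defaults to the first measurement.
#' @param p0 initial estimate variance (> 0).
#' @return Numeric vector of state estimates, one per measurement.
#' @examples
#' kalman_smooth(c(0, 1), q = 1, r = 1, x0 = 0, p0 = 1)  # 0, 0.625
#' @export
kalman_smooth <- function(series, q, r, x0 = series[1], p0 = 1) {
  if (length(series) == 0L) stop("`series` must be non-empty")
  if (!is.numeric(series) || anyNA(series)) stop("`series` must be numeric without NA")
  if (q <= 0 || r <= 0 || p0 <= 0) stop("variances `q`, `r`, `p0` must be positive")
  n <- length(series)
  out <- numeric(n)
  x <- x0
  p <- p0
  for (i in seq_len(n)) {
    p_pred <- p + q
    k <- p_pred / (p_pred + r)
    x <- x + k * (series[i] - x)
    p <- (1 - k) * p_pred
    out[i] <- x
  }
  out
}

#' Normalize raw counts to the dimensionless unit scale
#'
#' Divides each axis by the fixed full-scale count 32768 (not a per-trace
#' maximum), so the +/-0.35 leveling thresholds are comparable across
#' recordings, then clips to \eqn{[-1, 1]}.
#'
#' @param trace a data frame with columns `t, ax, ay, az` (raw counts).
#' @param config a [sensor_config()].
#' @return The trace with `ax, ay, az` replaced by normalized values.
#' @export
normalize_counts <- function(trace, config = sensor_config()) {
  if (nrow(trace) == 0L) stop("`trace` must be non-empty")
  for (axis in c("ax", "ay", "az")) {
    v <- trace[[axis]] / FULL_SCALE_COUNT
    trace[[axis]] <- pmin(1, pmax(-1, v))
  }
  trace
}

FULL_SCALE_COUNT <- 32768

#' Level a normalized value into {-1, 0, +1}
#'
#' Values strictly greater than `+threshold` map to +1, strictly below
#' `-threshold` to -1, and everything in between — including the boundaries
#' themselves — to 0.
#'
#' @param value numeric vector on the normalized scale.
#' @param threshold band half-width (> 0), default 0.35.
#' @return Integer vector over \{-1, 0, 1\}.
#' @examples
#' levelize(c(0.5, 0.35, -0.36))  # 1 0 -1
#' @export
levelize <- function(value, threshold = 0.35) {
  stopifnot(threshold > 0)
  (value > threshold) - (value < -threshold)
}

#' Preprocess one raw channel into leveled ternary triples
#'
#' Composition of the three preprocessing stages applied axis-wise: Kalman
#' smoothing, fixed full-scale normalization, and leveling. Output has one
#' row per input sample and each stage is causal (the estimate at index i
#' depends only on samples up to i).
#'
#' @param trace data frame with columns `t, ax, ay, az`, raw integer counts,
#'   `t` monotone non-decreasing.
#' @param config a [sensor_config()]; `mode = "left"` inverts the x axis
#'   before leveling.
#' @return Data frame with columns `t, lx, ly, lz`, each level in
#'   \{-1, 0, 1\}.
#' @export
preprocess_trace <- function(trace, config = sensor_config()) {
  validate_raw_trace(trace)
  scale2 <- FULL_SCALE_COUNT^2
  out <- data.frame(t = trace$t)
  lev <- list()
  for (axis in c("ax", "ay", "az")) {
    smoothed <- kalman_smooth(trace[[axis]],
                              q = config$kalman_q * scale2,
                              r = config$kalman_r * scale2)
    v <- pmin(1, pmax(-1, smoothed / FULL_SCALE_COUNT))
    lev[[axis]] <- v
  }
  if (config$mode == "left") lev$ax <- -lev$ax
  out$lx <- levelize(lev$ax, config$level_threshold)
  out$ly <- levelize(lev$ay, config$level_threshold)
  out$lz <- levelize(lev$az, config$level_threshold)
  out
}

validate_raw_trace <- function(trace) {
  req <- c("t", "ax", "ay", "az")
  missing_cols <- setdiff(req, names(trace))
  if (length(missing_cols) > 0)
    stop("trace is missing column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(trace) == 0L) stop("`trace` must be non-empty")
  if (is.unsorted(trace$t))
    stop("timestamps `t` must be monotone non-decreasing")
  for (axis in c("ax", "ay", "az")) {
    v <- trace[[axis]]
    if (anyNA(v)) stop("missing samples in `", axis, "` are not supported")
    bad <- which(abs(v) > FULL_SCALE_COUNT)
    if (length(bad) > 0)
      stop(sprintf("count %s in `%s` at row %d is outside [-32768, 32768]",
                   format(v[bad[1]]), axis, bad[1]))
  }
  invisible(trace)
}
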