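#' Construct a step template
#'
#' A step template pairs an ordered list of forearm symbol classes with an
#' ordered list of upper-arm classes; both channels must match simultaneously
#' over the same window for the step to pass.
#'
#' @param id label, e.g. `"Step 1"` or `"Steps 1-2"`.
#' @param forearm_classes character vector of forearm class symbols, in order.
#' @param upper_classes character vector of upper-arm class symbols, in order.
#' @return An object of class `step_template`.
#' @export
step_template <- function(id, forearm_classes, upper_classes) {
  stopifnot(length(forearm_classes) >= 1, length(upper_classes) >= 1)
  validate_channel_symbols(forearm_classes, "forearm", id)
  validate_channel_symbols(upper_classes, "upperarm", id)
  structure(list(id = id,
                 forearm_classes = forearm_classes,
                 upper_classes = upper_classes),
            class = "step_template")
}

validate_channel_symbols <- function(symbols, channel, where) {
  tab <- labeling_table()
  alphabet <- if (channel == "forearm") tab$forearm else tab$upperarm
  bad <- setdiff(symbols, alphabet)
  if (length(bad) > 0)
    stop(sprintf("invalid %s symbol '%s' in template '%s'",
                 channel, bad[1], where))
  invisible(symbols)
}

#' @export
print.step_template <- function(x, ...) {
  cat(sprintf("<step_template> %s: {%s} (+) {%s}\n", x$id,
              paste(x$forearm_classes, collapse = "-"),
              paste(x$upper_classes, collapse = "-")))
  invisible(x)
}

#' Built-in throwing-action template database
#'
#' Returns the reference database: the six numbered phase templates (class
#' orders follow the per-step sequence definitions, read in time order), the
#' 13 sub-step/transition templates exactly as printed in their original
#' enumeration, the erroneous-action definitions for Steps 0-6, and the
#' registered deviant patterns used for specific error messages.
#'
#' Phase templates (time order, forearm (+) upper arm):
#' Step 1 wind-up \{E-P\}(+)\{p\}; Step 2 stride \{A-M-Y\}(+)\{a-k\};
#' Step 3 arm cocking \{H-B-G\}(+)\{r-y-m\}; Step 4 arm acceleration
#' \{M-F-L-D\}(+)\{y-r\}; Step 5 arm deceleration \{A\}(+)\{a\};
#' Step 6 follow-through \{K\}(+)\{k\}.
#'
#' The 13 sub-templates are retained verbatim; note their printed enumeration
#' is not a consistent temporal chaining of the phase sequences (e.g.
#' "Steps 1-2 = \{Y-E\}" cannot follow "Step 1 = \{E-P\}" in time), so they
#' are scored as continuity diagnostics while verdicts come from the six
#' phase templates (see [recognize_throw()]).
#'
#' @return An object of class `template_db` with elements `phase_templates`
#'   (list of 6), `sub_templates` (list of 13), `error_defs` (data frame),
#'   `error_patterns` (list of registered deviant-pattern rules), and
#'   `standing` (per-channel standing-posture symbols).
#' @export
builtin_db <- function() {
  phase <- list(
    step_template("Step 1", c("E", "P"), "p"),
    step_template("Step 2", c("A", "M", "Y"), c("a", "k")),
    step_template("Step 3", c("H", "B", "G"), c("r", "y", "m")),
    step_template("Step 4", c("M", "F", "L", "D"), c("y", "r")),
    step_template("Step 5", "A", "a"),
    step_template("Step 6", "K", "k"))
  sub <- list(
    step_template("Step 1",   c("E", "P"), "p"),
    step_template("Steps 1-2", c("Y", "E"), c("k", "p")),
    step_template("Step 2.1", c("M", "Y"), "k"),
    step_template("Step 2.2", c("A", "M"), c("a", "k")),
    step_template("Steps 2-3", c("G", "A"), c("m", "a")),
    step_template("Step 3.1", c("B", "G"), c("y", "m")),
    step_template("Step 3.2", c("H", "B"), c("r", "y")),
    step_template("Steps 3-4", c("D", "H"), "r"),
    step_template("Step 4.1", c("L", "D"), "r"),
    step_template("Step 4.2", c("F", "L"), c("y", "r")),
    step_template("Step 4.3", c("M", "F"), "y"),
    step_template("Step 5",   c("A", "M"), c("a", "y")),
    step_template("Step 6",   c("K", "A"), c("k", "a")))
  error_defs <- data.frame(
    step = c(0L, 1L, 2L, 2L, 3L, 3L, 3L, 4L, 4L, 5L, 6L, 6L),
    process = c("Standing",
                "Standing -> forearm up",
                rep("Forearm up -> hands flat", 2),
                rep("Hands flat -> maximal external rotation", 3),
                rep("Maximal external rotation -> ball release", 2),
                "Ball release -> maximal internal rotation",
                rep("Maximal internal rotation -> extending", 2)),
    message = c("Worn too inside or outside",
                "Error-1",
                "Error-2", "Inverted W",
                "Error-3", "Elbow is too low", "Forearm flyout",
                "Error-4", "Elbow is not high enough",
                "Error-5",
                "Error-6", "No follow-through"),
    stringsAsFactors = FALSE)
  error_patterns <- list(
    list(step = 4L, rule = "forearm_absent_upper_ok",
         message = "Elbow is not high enough",
         display = "Elbow is not enough high"),
    list(step = 6L, rule = "all_rest",
         message = "No follow-through",
         display = "No follow-through"))
  structure(list(phase_templates = phase,
                 sub_templates = sub,
                 error_defs = error_defs,
                 error_patterns = error_patterns,
                 standing = c(forearm = "E", upperarm = "e")),
            class = "template_db")
}

#' @export
print.template_db <- function(x, ...) {
  cat(sprintf("<template_db> %d phase templates, %d sub-templates, %d error definitions\n",
              length(x$phase_templates), length(x$sub_templates),
              nrow(x$error_defs)))
  for (tmpl in x$phase_templates) print(tmpl)
  invisible(x)
}

#' Expand a template's classes into a concrete symbol-sequence fragment
#'
#' Repeats each forearm class by its requested run length; the upper-arm
#' classes are distributed as evenly as possible over the same total length
#' so both channels span the same window.
#'
#' @param tmpl a [step_template()].
#' @param run_lengths positive integers, one per forearm class.
#' @return A [throw_seq_pair()] fragment.
#' @examples
#' expand_template(builtin_db()$phase_templates[[1]], c(2, 2))  # "EEPP" / "pppp"
#' @export
expand_template <- function(tmpl, run_lengths) {
  if (length(run_lengths) != length(tmpl$forearm_classes))
    stop("need one run length per forearm class")
  if (any(run_lengths < 1)) stop("run lengths must be positive")
  run_lengths <- as.integer(run_lengths)
  fore <- paste(rep(tmpl$forearm_classes, run_lengths), collapse = "")
  total <- sum(run_lengths)
  upper <- paste(rep(tmpl$upper_classes,
                     even_allocation(total, length(tmpl$upper_classes))),
                 collapse = "")
  throw_seq_pair(fore, upper)
}

# Split `total` into `k` non-negative integers as evenly as possible,
# earlier slots taking the remainder.
even_allocation <- function(total, k) {
  base <- total %/% k
  rem <- total %% k
  base + as.integer(seq_len(k) <= rem)
}

#' Save a template database to JSON
#'
#' @param db a `template_db`.
#' @param path output file path.
#' @export
save_db <- function(db, path) {
  ser <- list(
    phase_templates = lapply(db$phase_templates, unclass),
    sub_templates = lapply(db$sub_templates, unclass),
    error_defs = db$error_defs,
    error_patterns = db$error_patterns,
    standing = as.list(db$standing))
  jsonlite::write_json(ser, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Load a template database from JSON
#'
#' Symbols are validated against the channel alphabets; an unknown symbol is
#' reported with the offending template named. Template order in the file is
#' preserved.
#'
#' @param path JSON file written by [save_db()].
#' @return A `template_db`.
#' @export
load_db <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(raw$phase_templates) || is.null(raw$sub_templates) ||
      is.null(raw$error_defs))
    stop("malformed template database: missing required section")
  parse_tmpl_list <- function(lst) {
    lapply(lst, function(x)
      step_template(x$id, unlist(x$forearm_classes), unlist(x$upper_classes)))
  }
  error_defs <- do.call(rbind, lapply(raw$error_defs, function(r)
    data.frame(step = as.integer(r$step), process = r$process,
               message = r$message, stringsAsFactors = FALSE)))
  patterns <- lapply(raw$error_patterns, function(p) {
    p <- lapply(p, unlist)
    p$step <- as.integer(p$step)
    p
  })
  structure(list(
    phase_templates = parse_tmpl_list(raw$phase_templates),
    sub_templates = parse_tmpl_list(raw$sub_templates),
    error_defs = error_defs,
    error_patterns = patterns,
    standing = unlist(raw$standing)),
    class = "template_db")
}
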