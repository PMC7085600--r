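# Canonical labeling table: one row per ternary status, both channels derived
# from it. Status 0-25 are the 26 non-rest triples; the all-zero rest triple
# carries the digit symbols '1' (forearm) and '2' (upper arm).
labeling_table <- function() {
  tab <- data.frame(
    status = 0:26,
    lx = c(0, 0, 1, 0, 0, -1, 0, 0, 0, 0, 1, 1, -1, -1, 1, 1, -1, -1,
           1, 1, 1, -1, 1, -1, -1, -1, 0),
    ly = c(0, 1, 0, 0, -1, 0, 1, 1, -1, -1, 0, 0, 0, 0, 1, -1, 1, -1,
           1, 1, -1, 1, -1, 1, -1, -1, 0),
    lz = c(1, 0, 0, -1, 0, 0, 1, -1, 1, -1, 1, -1, 1, -1, 0, 0, 0, 0,
           1, -1, 1, 1, -1, -1, 1, -1, 0),
    forearm = c(LETTERS[1:26], "1"),
    upperarm = c(letters[1:26], "2"),
    stringsAsFactors = FALSE)
  tab
}

.label_env <- new.env(parent = emptyenv())

label_lookup <- function() {
  if (is.null(.label_env$tab)) {
    tab <- labeling_table()
    key <- paste(tab$lx, tab$ly, tab$lz)
    .label_env$tab <- tab
    .label_env$fore <- setNames(tab$forearm, key)
    .label_env$upper <- setNames(tab$upperarm, key)
    .label_env$inv <- setNames(
      lapply(seq_len(nrow(tab)), function(i) c(tab$lx[i], tab$ly[i], tab$lz[i])),
      paste0(tab$forearm, tab$upperarm))
  }
  .label_env
}

#' Map a leveled triple to its channel symbol
#'
#' Implements the 27-symbol labeling per channel: each ternary triple
#' \eqn{(l_x, l_y, l_z) \in \{-1,0,1\}^3} maps to one uppercase letter or the
#' digit '1' (forearm), or one lowercase letter or the digit '2' (upper arm).
#' The all-zero rest triple takes the digit.
#'
#' @param triple integer vector of length 3 over \{-1, 0, 1\}, or a matrix /
#'   data frame with three columns for vectorized use.
#' @param channel `"forearm"` or `"upperarm"`.
#' @return Character vector of single symbols.
#' @examples
#' triple_to_symbol(c(0, 0, 1), "forearm")    # "A"
#' triple_to_symbol(c(1, -1, 0), "upperarm")  # "p"
#' @export
triple_to_symbol <- function(triple, channel = c("forearm", "upperarm")) {
  channel <- match.arg(channel)
  if (is.data.frame(triple)) triple <- as.matrix(triple)
  if (is.null(dim(triple))) triple <- matrix(triple, ncol = 3, byrow = TRUE)
  if (!all(triple %in% c(-1L, 0L, 1L)))
    stop("triple components must be in {-1, 0, 1}")
  env <- label_lookup()
  map <- if (channel == "forearm") env$fore else env$upper
  key <- paste(triple[, 1], triple[, 2], triple[, 3])
  unname(map[key])
}

#' Invert a symbol back to its leveled triple and channel
#'
#' Exact inverse of [triple_to_symbol()] over the 54 valid symbols.
#'
#' @param symbol a single character from either channel's alphabet.
#' @return List with `triple` (integer length 3) and `channel`.
#' @export
symbol_to_triple <- function(symbol) {
  stopifnot(is.character(symbol), length(symbol) == 1L, nchar(symbol) == 1L)
  env <- label_lookup()
  tab <- env$tab
  if (symbol %in% tab$forearm) {
    i <- match(symbol, tab$forearm)
    channel <- "forearm"
  } else if (symbol %in% tab$upperarm) {
    i <- match(symbol, tab$upperarm)
    channel <- "upperarm"
  } else {
    stop("unknown symbol: '", symbol, "'")
  }
  list(triple = c(tab$lx[i], tab$ly[i], tab$lz[i]), channel = channel)
}

#' Build the two-channel symbol sequence for one recording
#'
#' Applies the labeling position-wise to time-aligned forearm and upper-arm
#' leveled traces (as returned by [preprocess_trace()]).
#'
#' @param forearm_triples,upper_triples data frames with columns
#'   `lx, ly, lz` (and optionally `t`), equal number of rows.
#' @return A `throw_seq_pair`: list with `forearm` and `upperarm` symbol
#'   strings of equal length.
#' @export
encode_pair <- function(forearm_triples, upper_triples) {
  if (nrow(forearm_triples) != nrow(upper_triples))
    stop("forearm and upper-arm traces must have equal length")
  lev_cols <- c("lx", "ly", "lz")
  if (nrow(forearm_triples) == 0L) return(throw_seq_pair("", ""))
  fore <- triple_to_symbol(as.matrix(forearm_triples[lev_cols]), "forearm")
  upper <- triple_to_symbol(as.matrix(upper_triples[lev_cols]), "upperarm")
  throw_seq_pair(paste(fore, collapse = ""), paste(upper, collapse = ""))
}

#' Construct a two-channel symbol sequence pair
#'
#' @param forearm,upperarm symbol strings of equal length over their
#'   respective alphabets.
#' @return An object of class `throw_seq_pair`.
#' @export
throw_seq_pair <- function(forearm, upperarm) {
  stopifnot(is.character(forearm), is.character(upperarm),
            length(forearm) == 1L, length(upperarm) == 1L)
  if (nchar(forearm) != nchar(upperarm))
    stop("channel sequences must have equal length")
  structure(list(forearm = forearm, upperarm = upperarm),
            class = "throw_seq_pair")
}

#' @export
print.throw_seq_pair <- function(x, ...) {
  cat(sprintf("<throw_seq_pair> %d samples\n", nchar(x$forearm)))
  abbr <- function(s) if (nchar(s) > 60) paste0(substr(s, 1, 57), "...") else s
  cat("  forearm:  ", abbr(x$forearm), "\n")
  cat("  upper arm:", abbr(x$upperarm), "\n")
  invisible(x)
}

#' Run-length encode a symbol sequence
#'
#' Lossless: [expand_runs()] of the result reproduces the input. Slower
#' throws produce longer runs of identical symbols, so run-compressed
#' sequences are the speed-invariant view used for template matching.
#'
#' @param seq a symbol string.
#' @return List with `symbols` (distinct-adjacent characters) and `lengths`
#'   (positive run counts).
#' @examples
#' compress_runs("EEEEPPPP")  # symbols E, P; lengths 4, 4
#' @export
compress_runs <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) == 0L) return(list(symbols = character(0), lengths = integer(0)))
  r <- rle(strsplit(seq, "")[[1]])
  list(symbols = r$values, lengths = r$lengths)
}

#' Expand a run-length encoding back to a string
#'
#' @param runs list with `symbols` and `lengths` as from [compress_runs()].
#' @return The expanded symbol string.
#' @export
expand_runs <- function(runs) {
  if (length(runs$symbols) == 0L) return("")
  if (any(runs$lengths < 1)) stop("run lengths must be positive")
  paste(rep(runs$symbols, runs$lengths), collapse = "")
}
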