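#' Longest-common-subsequence length
#'
#' Length of the longest sequence obtainable from both `a` and `b` by
#' deletions only, computed bottom-up by dynamic programming (compiled).
#' Satisfies the recursion: LCS(m, n) = 0 if m = 0 or n = 0;
#' LCS(m-1, n-1) + 1 if \eqn{a_m = b_n}; max(LCS(m-1, n), LCS(m, n-1))
#' otherwise.
#'
#' @param a,b character strings (empty strings allowed).
#' @return Non-negative integer.
#' @examples
#' lcs_length("EEPP", "EEEPPPP")  # 4
#' lcs_length("MYAK", "AKMY")     # 2
#' @export
lcs_length <- function(a, b) {
  stopifnot(is.character(a), is.character(b),
            length(a) == 1L, length(b) == 1L)
  .lcs_length_cpp(a, b)
}

#' Full LCS dynamic-programming matrix
#'
#' The (m+1) x (n+1) cumulative-length matrix filled from the upper left to
#' the lower right; cell (m+1, n+1) is the LCS length. Pure-R reference kept
#' for inspection of the recursion; [lcs_length()] is the fast path.
#'
#' @param a,b character strings.
#' @return Integer matrix with first row and column zero, entries
#'   non-decreasing along rows and columns.
#' @export
lcs_matrix <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  m <- length(av); n <- length(bv)
  mat <- matrix(0L, m + 1, n + 1)
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      mat[i + 1, j + 1] <- if (av[i] == bv[j]) mat[i, j] + 1L
                           else max(mat[i, j + 1], mat[i + 1, j])
    }
  }
  mat
}

#' LCS similarity between an observed segment and an expanded template
#'
#' Ratio of the LCS length to the expanded template length; 1 when the
#' template is a subsequence of the segment, 0 when they share no symbols.
#'
#' @param segment observed symbol string.
#' @param template_expanded expanded template string (non-empty).
#' @return List with `lcs_len`, `template_len`, `ratio`.
#' @export
lcs_similarity <- function(segment, template_expanded) {
  if (nchar(template_expanded) == 0L) stop("expanded template must be non-empty")
  len <- lcs_length(segment, template_expanded)
  list(lcs_len = len,
       template_len = nchar(template_expanded),
       ratio = len / nchar(template_expanded))
}

# Expand template classes to an expansion of exactly `n` symbols sized to the
# observed segment: each class gets its observed symbol count within the
# segment, and the remaining (non-class) mass is spread over the classes by
# largest remainder. If no class symbol occurs, fall back to an even split.
# This keeps the score near 1 - (fraction of off-template symbols) whatever
# the per-class run proportions are, so matching stays speed-invariant.
expansion_for_segment <- function(segment_chars, classes) {
  n <- length(segment_chars)
  counts <- vapply(classes, function(cl) sum(segment_chars == cl), integer(1))
  if (sum(counts) == 0L) {
    alloc <- even_allocation(n, length(classes))
  } else {
    leftover <- n - sum(counts)
    extra <- leftover * counts / sum(counts)
    alloc <- counts + floor(extra)
    short <- n - sum(alloc)
    if (short > 0) {
      order_idx <- order(extra - floor(extra), decreasing = TRUE)
      alloc[order_idx[seq_len(short)]] <- alloc[order_idx[seq_len(short)]] + 1L
    }
  }
  paste(rep(classes, alloc), collapse = "")
}

#' Match a two-channel segment against a step template
#'
#' A step passes only when the forearm and the upper-arm channels
#' simultaneously reach LCS similarity of at least `theta` against their
#' respective class expansions sized to the segment. A cheap
#' alphabet-intersection screen skips the dynamic program when a channel
#' shares no symbol with its template classes.
#'
#' @param pair_segment a [throw_seq_pair()] fragment.
#' @param tmpl a [step_template()].
#' @param theta similarity threshold in (0, 1]; default 0.7.
#' @return Logical scalar; attribute `"scores"` carries both channel ratios.
#' @export
match_step <- function(pair_segment, tmpl, theta = 0.7) {
  stopifnot(theta > 0, theta <= 1)
  score_channel <- function(seq, classes) {
    chars <- strsplit(seq, "")[[1]]
    if (length(chars) == 0L) return(0)
    if (!any(chars %in% classes)) return(0)  # pre-gate: no shared alphabet
    expansion <- expansion_for_segment(chars, classes)
    lcs_similarity(seq, expansion)$ratio
  }
  s_fore <- score_channel(pair_segment$forearm, tmpl$forearm_classes)
  s_upper <- score_channel(pair_segment$upperarm, tmpl$upper_classes)
  structure(s_fore >= theta && s_upper >= theta,
            scores = c(forearm = s_fore, upperarm = s_upper))
}
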