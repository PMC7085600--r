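# Shared fixtures built in code.

default_config <- function(mode = "right") sensor_config(mode = mode)

# Symbol pair produced by the full preprocessing of a generated throw.
pipeline_pair <- function(thr, config = default_config(thr$profile$handedness)) {
  encode_pair(preprocess_trace(thr$forearm, config),
              preprocess_trace(thr$upperarm, config))
}

# Constant leveled trace at a given symbol's triple.
constant_levels <- function(symbol, n) {
  tr <- symbol_to_triple(symbol)$triple
  data.frame(lx = rep(tr[1], n), ly = rep(tr[2], n), lz = rep(tr[3], n))
}

# Brute-force LCS oracle: enumerate all subsequences of the shorter string
# and keep the longest that is also a subsequence of the other.
lcs_bruteforce <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  if (length(av) > length(bv)) { tmp <- av; av <- bv; bv <- tmp }
  m <- length(av)
  if (m == 0) return(0L)
  is_subseq <- function(x, y) {
    j <- 1L
    for (ch in y) {
      if (j <= length(x) && x[j] == ch) j <- j + 1L
    }
    j > length(x)
  }
  best <- 0L
  for (mask in 0:(2^m - 1)) {
    sub <- av[bitwAnd(mask, 2^(seq_len(m) - 1)) > 0]
    if (length(sub) > best && is_subseq(sub, bv)) best <- length(sub)
  }
  best
}

# Identification counts from a three-user field evaluation (50 throws per
# user), shipped with the package.
evaluation_counts <- function() {
  read.csv(system.file("extdata", "evaluation_counts.csv", package = "throwrec"))
}
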