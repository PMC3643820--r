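# Independent oracles used across the suite.

# Exhaustive label-shuffle tail: enumerate every way of placing n direction
# labels among N genes (membership = first K genes) with utils::combn and
# count the overlap directly. Returns P(overlap >= a) ("upper") or
# P(overlap <= a) ("lower").
enumerate_shuffle_tail <- function(N, K, n, a, side = "upper") {
  if (n == 0L) {
    ov <- 0L
    return(if (side == "upper") mean(ov >= a) else mean(ov <= a))
  }
  subsets <- utils::combn(N, n)
  ov <- colSums(subsets <= K)
  if (side == "upper") mean(ov >= a) else mean(ov <= a)
}

# For one (N, n), enumerate all subsets once and return the full table of
# P(overlap >= j) for j in 0..n and every K in 1..N (rows = j+1, cols = K).
# Works by tabulating the j-th smallest element of each subset: the overlap
# with {1..K} is >= j exactly when that element is <= K.
enumerate_upper_tail_table <- function(N, n) {
  subsets <- utils::combn(N, n)
  n_sub <- ncol(subsets)
  out <- matrix(NA_real_, nrow = n + 1L, ncol = N)
  out[1L, ] <- 1  # overlap >= 0 always
  for (j in seq_len(n)) {
    jth <- if (n == 1L) subsets else subsets[j, ]
    out[j + 1L, ] <- cumsum(tabulate(jth, nbins = N)) / n_sub
  }
  out
}

# Textbook Pearson chi-squared by the sum((O-E)^2/E) expansion.
brute_chi2 <- function(a, b, c, d) {
  o <- matrix(c(a, c, b, d), nrow = 2)
  e <- outer(rowSums(o), colSums(o)) / sum(o)
  sum((o - e)^2 / e)
}

# Minimal expression matrix with named dimensions.
make_matrix <- function(values, probes, samples) {
  matrix(values, nrow = length(probes), ncol = length(samples),
         dimnames = list(probes, samples))
}

# Template data frame without going through a file.
make_template <- function(ctrl, expt, experiment_id = "ex") {
  out <- data.frame(sample_id = c(ctrl, expt),
                    role = rep(c("control", "experimental"),
                               c(length(ctrl), length(expt))),
                    stringsAsFactors = FALSE)
  attr(out, "experiment_id") <- experiment_id
  out
}

# Write series-matrix lines to a temp file and return the path.
write_series_lines <- function(lines) {
  path <- tempfile(fileext = ".txt")
  writeLines(lines, path)
  path
}
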