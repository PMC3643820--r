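# Label-shuffling permutation test for the L1/regulation overlap and the
# exact hypergeometric tail used as its closed-form check.

#' Permutation test of the library/regulation overlap by label shuffling
#'
#' Keeps library membership fixed and uniformly re-assigns the regulation
#' labels (`down`/`up`/`neutral`) across genes in each replicate; the test
#' statistic is the overlap count between membership and the tested
#' direction (cell `a` of the contingency table). The tail is one-sided in
#' the direction of the observed deviation from expectation: replicates with
#' overlap `>=` observed are counted when the observed overlap is at or
#' above its expectation, and `<=` observed otherwise. The permutation
#' p-value is `n_as_extreme / n_replicates` (or `(n_as_extreme + 1) /
#' (n_replicates + 1)` with `plus_one = TRUE` for a guaranteed-positive
#' estimate).
#'
#' Because only the overlap between a fixed membership set and the shuffled
#' direction labels matters, the null distribution is exactly
#' hypergeometric; [hypergeometric_tail()] provides the closed form this
#' Monte Carlo estimate converges to.
#'
#' @param labels Character vector of per-gene labels over the testable
#'   universe, values in `down`, `up`, `neutral`.
#' @param membership Logical vector, same length: gene in the library?
#' @param direction Tested direction, `"down"` or `"up"`.
#' @param n_replicates Number of shuffles (default 100,000).
#' @param seed Optional integer seed; the result is reproducible given the
#'   seed. With `NULL` the current RNG stream is used.
#' @param plus_one Use the (r+1)/(n+1) estimator instead of r/n.
#' @return List with `observed_overlap`, `expected_overlap`,
#'   `n_replicates`, `n_as_extreme`, `perm_p`, `side` (`"upper"`/`"lower"`)
#'   and `seed`.
#' @export
permutation_test <- function(labels, membership, direction = c("down", "up"),
                             n_replicates = 100000L, seed = NULL,
                             plus_one = FALSE) {
  direction <- match.arg(direction)
  if (length(labels) != length(membership))
    stop("labels and membership must cover the same universe", call. = FALSE)
  if (!all(labels %in% c("down", "up", "neutral")))
    stop("labels must be 'down', 'up' or 'neutral'", call. = FALSE)
  n_replicates <- as.integer(n_replicates)
  if (is.na(n_replicates) || n_replicates < 1L)
    stop("n_replicates must be a positive integer", call. = FALSE)
  membership <- as.logical(membership)
  if (!is.null(seed)) set.seed(seed)

  N <- length(labels)
  n_dir <- sum(labels == direction)
  observed <- sum(membership & labels == direction)
  expected <- n_dir * sum(membership) / N
  side <- if (observed >= expected) "upper" else "lower"

  r <- 0L
  if (n_dir == 0L) {
    # every shuffle reproduces overlap 0
    r <- n_replicates
  } else {
    for (i in seq_len(n_replicates)) {
      ov <- sum(membership[sample.int(N, n_dir)])
      if (side == "upper") {
        if (ov >= observed) r <- r + 1L
      } else {
        if (ov <= observed) r <- r + 1L
      }
    }
  }
  perm_p <- if (plus_one) (r + 1) / (n_replicates + 1) else r / n_replicates
  list(observed_overlap = observed, expected_overlap = expected,
       n_replicates = n_replicates, n_as_extreme = r, perm_p = perm_p,
       side = side, seed = if (is.null(seed)) NA_integer_ else seed)
}

#' Exact hypergeometric tail probability
#'
#' Tail probability of the overlap `X` between a fixed set of size `col1`
#' and a uniformly drawn set of size `row1` in a universe of `n_total`
#' elements, i.e. `X ~ Hypergeometric(n_total, col1, row1)`. Computed by
#' direct summation of log-binomial terms. This is the closed form of the
#' label-shuffling null of [permutation_test()].
#'
#' @param a Overlap count at which the tail is evaluated.
#' @param row1 Size of the drawn set (e.g. genes regulated in a direction).
#' @param col1 Size of the fixed set (e.g. library genes in the universe).
#' @param n_total Universe size.
#' @param side `"upper"` for `P(X >= a)`, `"lower"` for `P(X <= a)`.
#' @return The tail probability.
#' @examples
#' hypergeometric_tail(28, 197, 1340, 20374, "upper")  # ~9.6e-5
#' @export
hypergeometric_tail <- function(a, row1, col1, n_total,
                                side = c("upper", "lower")) {
  side <- match.arg(side)
  vals <- c(a = a, row1 = row1, col1 = col1, n_total = n_total)
  if (anyNA(vals) || any(vals < 0) || any(vals != round(vals)))
    stop("hypergeometric_tail expects non-negative integers", call. = FALSE)
  if (row1 > n_total || col1 > n_total)
    stop("inconsistent margins: row1 and col1 cannot exceed n_total",
         call. = FALSE)
  if (a > min(row1, col1))
    stop("inconsistent margins: a cannot exceed min(row1, col1)",
         call. = FALSE)
  k_min <- max(0, row1 + col1 - n_total)
  k_max <- min(row1, col1)
  k <- if (side == "upper") a:k_max else k_min:a
  log_terms <- lchoose(col1, k) + lchoose(n_total - col1, row1 - k) -
    lchoose(n_total, row1)
  min(1, sum(exp(log_terms)))
}

#' Attach permutation p-values to an enrichment result table
#'
#' Runs [permutation_test()] for every non-degenerate row of an enrichment
#' table, shuffling the experiment's gene labels against the corresponding
#' library membership.
#'
#' @param results Enrichment table from [analyze_experiment()] for one
#'   experiment.
#' @param calls The experiment's gene-level regulation table.
#' @param libraries Named list of [l1_library] objects (`all`, `sense`,
#'   `antisense`).
#' @param n_replicates Shuffles per row.
#' @param seed Optional seed set once before the first row, so the whole
#'   table is reproducible.
#' @param plus_one Passed to [permutation_test()].
#' @return `results` with the `perm_p` column filled in.
#' @export
attach_permutation_p <- function(results, calls, libraries,
                                 n_replicates = 100000L, seed = NULL,
                                 plus_one = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  gene_col <- if ("gene" %in% names(calls)) "gene" else "id"
  universe <- calls[calls$call != "untestable", , drop = FALSE]
  for (i in seq_len(nrow(results))) {
    if (isTRUE(results$degenerate[i])) next
    lib <- libraries[[results$library[i]]]
    membership <- universe[[gene_col]] %in% lib$genes
    pt <- permutation_test(universe$call, membership,
                           results$direction[i],
                           n_replicates = n_replicates, seed = NULL,
                           plus_one = plus_one)
    results$perm_p[i] <- pt$perm_p
  }
  results
}
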