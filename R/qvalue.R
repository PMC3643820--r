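# Storey FDR: bootstrap estimation of the null proportion pi0 and q-value
# computation by the step-up recursion.

#' Estimate the null proportion pi0 by the bootstrap-lambda method
#'
#' For each tuning value `lambda`, the natural estimate is
#' `pi0(lambda) = #\{p > lambda\} / (m * (1 - lambda))`. The bootstrap
#' selects the `lambda` whose estimate has the smallest bootstrap mean
#' squared error around the minimum of `pi0(lambda)` over the grid (the
#' plug-in proxy for the true pi0), and returns `pi0(lambda*)` clipped to
#' (0, 1]. This is the "bootstrap" pi0 option of the QVALUE methodology, as
#' opposed to the smoother option.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param lambda Strictly increasing grid in \[0, 1); default
#'   `seq(0, 0.90, by = 0.05)`.
#' @param n_boot Number of bootstrap resamples.
#' @param seed Optional integer seed for the resampling.
#' @return List with `pi0`, `lambda_star`, `pi0_lambda` (the grid estimates),
#'   `mse` (bootstrap MSE per grid point), `n_boot` and `seed`.
#' @export
estimate_pi0_bootstrap <- function(p, lambda = seq(0, 0.90, by = 0.05),
                                   n_boot = 100L, seed = NULL) {
  if (length(p) == 0L)
    stop("empty p-value vector", call. = FALSE)
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  if (length(lambda) < 1L || is.unsorted(lambda, strictly = TRUE) ||
      min(lambda) < 0 || max(lambda) >= 1)
    stop("lambda grid must be strictly increasing within [0, 1)",
         call. = FALSE)
  n_boot <- as.integer(n_boot)
  if (is.na(n_boot) || n_boot < 1L)
    stop("n_boot must be a positive integer", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  m <- length(p)
  pi0_of <- function(pv) {
    vapply(lambda, function(l) sum(pv > l) / (m * (1 - l)), numeric(1))
  }
  pi0_lambda <- pi0_of(p)
  min_pi0 <- min(pi0_lambda)

  mse <- numeric(length(lambda))
  for (b in seq_len(n_boot)) {
    pb <- p[sample.int(m, m, replace = TRUE)]
    mse <- mse + (pi0_of(pb) - min_pi0)^2
  }
  mse <- mse / n_boot
  i_star <- which.min(mse)
  pi0 <- min(pi0_lambda[i_star], 1)
  if (pi0 <= 0) {
    # happens when no p-value exceeds the largest lambda (typically very
    # small m); fall back to the conservative pi0 = 1 (plain BH behaviour)
    warning("pi0 estimate was non-positive; falling back to pi0 = 1")
    pi0 <- 1
  }
  list(pi0 = pi0, lambda_star = lambda[i_star], pi0_lambda = pi0_lambda,
       mse = mse, n_boot = n_boot,
       seed = if (is.null(seed)) NA_integer_ else seed)
}

#' Compute q-values from p-values and a pi0 estimate
#'
#' With the p-values sorted ascending, `q(m) = min(pi0 * p(m), 1)` and
#' `q(i) = min(pi0 * m * p(i) / i, q(i+1))`; the result is mapped back to
#' the input order. Sorted q-values are therefore monotone non-decreasing
#' and never exceed 1.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param pi0 Estimated proportion of true nulls, in (0, 1\].
#' @return Numeric vector of q-values in input order.
#' @examples
#' compute_qvalues(c(0.01, 0.02, 0.03, 0.04), pi0 = 1)  # all 0.04
#' @export
compute_qvalues <- function(p, pi0 = 1) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  if (!is.numeric(pi0) || length(pi0) != 1L || pi0 <= 0 || pi0 > 1)
    stop("pi0 must be a single value in (0, 1]", call. = FALSE)
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- pi0 * m * ps / seq_len(m)
  q[m] <- min(pi0 * ps[m], 1)
  if (m > 1L) {
    for (i in (m - 1):1) q[i] <- min(q[i], q[i + 1])
  }
  q <- pmin(q, 1)
  out <- numeric(m)
  out[ord] <- q
  out
}

#' Attach q-values to an enrichment result table
#'
#' Estimates pi0 from the permutation p-values of all non-degenerate rows
#' (jointly across experiments, directions and libraries, mirroring a screen
#' of many knockdown experiments corrected as one family) and fills in the
#' `q_value` column.
#'
#' @param results Enrichment table with `perm_p` filled in, typically rows
#'   from several experiments bound together.
#' @param pi0 Optional fixed pi0; when `NULL` it is estimated with
#'   [estimate_pi0_bootstrap()].
#' @param lambda,n_boot,seed Passed to [estimate_pi0_bootstrap()].
#' @return `results` with `q_value` filled in; the pi0 used is stored in
#'   attribute `pi0`.
#' @export
attach_qvalues <- function(results, pi0 = NULL,
                           lambda = seq(0, 0.90, by = 0.05), n_boot = 100L,
                           seed = NULL) {
  usable <- !is.na(results$perm_p)
  if (!any(usable))
    stop("no permutation p-values available for q-value computation",
         call. = FALSE)
  p <- results$perm_p[usable]
  if (is.null(pi0))
    pi0 <- estimate_pi0_bootstrap(p, lambda = lambda, n_boot = n_boot,
                                  seed = seed)$pi0
  results$q_value[usable] <- compute_qvalues(p, pi0)
  attr(results, "pi0") <- pi0
  results
}
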