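# Per-row pooled two-sample t-tests between control and experimental samples
# and conversion to up/down/neutral regulation calls.

#' Pooled two-sample t-test for one gene or probe
#'
#' Classic equal-variance (Student) two-sample t-test. Missing values are
#' removed per group before testing. The statistic is oriented as
#' experimental minus control: `t = (mean(y) - mean(x)) / se`, with the
#' pooled variance on `n1 + n2 - 2` degrees of freedom and a two-sided
#' p-value. A row is untestable when either group retains fewer than two
#' values or the pooled variance is exactly zero.
#'
#' @param x Numeric vector of control values.
#' @param y Numeric vector of experimental values.
#' @return A list with elements `t`, `p`, `df`, `mean_control`,
#'   `mean_experimental` and logical `untestable` (when `TRUE`, `t` and `p`
#'   are `NA`).
#' @examples
#' two_sample_t(c(10.2, 9.8, 10.0), c(12.1, 11.9, 12.3))
#' two_sample_t(c(1, 1), c(2, 2))$untestable  # zero pooled variance
#' @export
two_sample_t <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y))
    stop("two_sample_t expects numeric vectors", call. = FALSE)
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  n1 <- length(x); n2 <- length(y)
  mx <- if (n1) mean(x) else NA_real_
  my <- if (n2) mean(y) else NA_real_
  if (n1 < 2L || n2 < 2L)
    return(list(t = NA_real_, p = NA_real_, df = NA_real_,
                mean_control = mx, mean_experimental = my, untestable = TRUE))
  df <- n1 + n2 - 2L
  s2 <- (sum((x - mx)^2) + sum((y - my)^2)) / df
  if (s2 == 0)
    return(list(t = NA_real_, p = NA_real_, df = df,
                mean_control = mx, mean_experimental = my, untestable = TRUE))
  tt <- (my - mx) / sqrt(s2 * (1 / n1 + 1 / n2))
  list(t = tt, p = 2 * stats::pt(-abs(tt), df), df = df,
       mean_control = mx, mean_experimental = my, untestable = FALSE)
}

# Vectorised pooled t over matrix rows; returns a data frame aligned with
# rownames(values). Cross-checked against stats::t.test in the test suite.
.row_pooled_t <- function(values, ctrl, expt) {
  xc <- values[, ctrl, drop = FALSE]
  xe <- values[, expt, drop = FALSE]
  n1 <- rowSums(is.finite(xc))
  n2 <- rowSums(is.finite(xe))
  mc <- rowMeans(xc, na.rm = TRUE)
  me <- rowMeans(xe, na.rm = TRUE)
  mc[n1 == 0L] <- NA_real_
  me[n2 == 0L] <- NA_real_
  ssc <- rowSums((xc - mc)^2, na.rm = TRUE)
  sse <- rowSums((xe - me)^2, na.rm = TRUE)
  df <- n1 + n2 - 2
  s2 <- ifelse(df > 0, (ssc + sse) / df, NA_real_)
  untestable <- n1 < 2L | n2 < 2L | (!is.na(s2) & s2 == 0)
  tt <- ifelse(untestable, NA_real_,
               (me - mc) / sqrt(s2 * (1 / n1 + 1 / n2)))
  pp <- ifelse(untestable, NA_real_, 2 * stats::pt(-abs(tt), df))
  data.frame(id = rownames(values), mean_control = mc, mean_experimental = me,
             t = tt, p = pp, untestable = untestable,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Call per-row regulation between control and experimental groups
#'
#' Runs the pooled two-sample t-test of [two_sample_t()] on every row of an
#' expression matrix and converts the result to a call: `up` when
#' `p < alpha` and the experimental mean exceeds the control mean, `down`
#' when `p < alpha` and it is lower, `neutral` otherwise (including an exact
#' mean tie), and `untestable` when the statistic is undefined. Significance
#' uses the strict inequality `p < alpha`.
#'
#' The matrix may be probe-level (collapse afterwards with
#' [collapse_to_genes()]) or already gene-level.
#'
#' @param values Numeric matrix, rows = probes or genes (rownames required),
#'   columns = samples (colnames required); missing values are `NA`.
#' @param template Sample template from [read_sample_template()], or any data
#'   frame with columns `sample_id` and `role`.
#' @param alpha Per-gene significance level for calling regulation.
#' @return A data frame with columns `id`, `mean_control`,
#'   `mean_experimental`, `t`, `p`, `call`, with attributes `experiment_id`
#'   and `alpha`.
#' @export
call_regulation <- function(values, template, alpha = 0.01) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs rownames and colnames", call. = FALSE)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("alpha must be a single value in (0, 1)", call. = FALSE)
  absent <- setdiff(template$sample_id, colnames(values))
  if (length(absent))
    stop("template sample(s) absent from expression matrix: ",
         paste(absent, collapse = ", "), call. = FALSE)
  ctrl <- template$sample_id[template$role == "control"]
  expt <- template$sample_id[template$role == "experimental"]
  res <- .row_pooled_t(values, ctrl, expt)
  call <- rep("neutral", nrow(res))
  sig <- !res$untestable & res$p < alpha
  call[sig & res$mean_experimental > res$mean_control] <- "up"
  call[sig & res$mean_experimental < res$mean_control] <- "down"
  call[res$untestable] <- "untestable"
  res$call <- call
  res$untestable <- NULL
  attr(res, "experiment_id") <- attr(template, "experiment_id")
  attr(res, "alpha") <- alpha
  res
}

#' Write a regulation table as TSV
#'
#' Columns: gene (or probe) identifier, group means, t statistic, p-value and
#' call.
#'
#' @param calls Regulation table from [call_regulation()] or
#'   [collapse_to_genes()].
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_regulation_table <- function(calls, file) {
  utils::write.table(calls, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
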