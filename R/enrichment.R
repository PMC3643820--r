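# Per-experiment 2x2 enrichment of an L1 host-gene library among regulated
# genes: contingency counts, Pearson chi-squared, odds ratio with Woolf CI.

#' Build the 2x2 contingency table for one direction and one library
#'
#' The universe is every gene with a testable call (`call != "untestable"`).
#' Crossing library membership with regulation in the tested direction gives
#' the four cells: `a` = library genes regulated in the direction, `b` =
#' library genes not so regulated, `c` = non-library genes regulated, `d` =
#' the remainder; the cells sum to the universe size.
#'
#' @param calls Gene-level regulation table (columns `gene`, `call`).
#' @param direction `"down"` or `"up"`.
#' @param library An [l1_library] object (or character vector of symbols).
#' @return Named integer vector `c(a, b, c, d)`.
#' @examples
#' calls <- data.frame(gene = paste0("G", 1:10),
#'                     call = c("down", "down", "down", rep("neutral", 7)))
#' lib <- l1_library(paste0("G", c(1, 2, 5, 6)))
#' build_contingency(calls, "down", lib)  # a=2 b=2 c=1 d=5
#' @export
build_contingency <- function(calls, direction = c("down", "up"), library) {
  direction <- match.arg(direction)
  if (inherits(library, "l1_library")) library <- library$genes
  gene_col <- if ("gene" %in% names(calls)) "gene" else "id"
  universe <- calls[calls$call != "untestable", , drop = FALSE]
  in_lib <- universe[[gene_col]] %in% library
  hit <- universe$call == direction
  a <- sum(in_lib & hit)
  b <- sum(in_lib) - a
  c <- sum(!in_lib & hit)
  d <- sum(!in_lib) - c
  if (a + b == 0L)
    stop("degenerate margin: no library genes in the testable universe",
         call. = FALSE)
  if (c + d == 0L)
    stop("degenerate margin: no non-library genes in the testable universe",
         call. = FALSE)
  c(a = a, b = b, c = c, d = d)
}

.check_table <- function(table) {
  if (is.matrix(table)) table <- c(a = table[1, 1], b = table[1, 2],
                                   c = table[2, 1], d = table[2, 2])
  table <- as.numeric(table[c("a", "b", "c", "d")])
  if (anyNA(table) || any(table < 0) || any(table != round(table)))
    stop("contingency table must hold non-negative integer cells a, b, c, d",
         call. = FALSE)
  names(table) <- c("a", "b", "c", "d")
  table
}

#' Pearson chi-squared test of a 2x2 table
#'
#' Pearson's chi-squared statistic on one degree of freedom, without
#' continuity correction; the p-value is the upper tail of the chi-squared
#' distribution. Both printed example tables of the screen this package
#' implements reproduce only without the Yates correction, which pins down
#' that choice.
#'
#' @param table Named vector `c(a, b, c, d)` (as from [build_contingency()])
#'   or a 2x2 matrix in the same layout.
#' @return List with `chi2` and `p_value`.
#' @examples
#' chi_squared_test(c(a = 28, b = 1312, c = 169, d = 18865))$p_value # 1.39e-5
#' @export
chi_squared_test <- function(table) {
  tb <- .check_table(table)
  m <- matrix(tb[c("a", "c", "b", "d")], nrow = 2)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("degenerate margin: chi-squared test undefined", call. = FALSE)
  ht <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(chi2 = unname(ht$statistic), p_value = unname(ht$p.value))
}

#' Odds ratio of a 2x2 table with Woolf confidence interval
#'
#' The odds ratio is the cross-product ratio `a*d / (b*c)`; the confidence
#' interval is the Woolf (log-OR) interval
#' `exp(log(OR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`. When any cell is
#' zero, the Haldane-Anscombe correction adds 0.5 to all four cells for the
#' odds ratio and interval only (the chi-squared test keeps raw counts).
#'
#' @param table Named vector `c(a, b, c, d)` or 2x2 matrix.
#' @param z Normal quantile for the interval; the default 1.959964 gives a
#'   95% interval.
#' @return List with `odds_ratio`, `ci_low`, `ci_high`.
#' @examples
#' odds_ratio_ci(c(a = 28, b = 1312, c = 169, d = 18865))$odds_ratio # 2.38
#' @export
odds_ratio_ci <- function(table, z = 1.959964) {
  tb <- .check_table(table)
  if (tb["a"] + tb["b"] == 0 || tb["c"] + tb["d"] == 0)
    stop("degenerate margin: odds ratio undefined", call. = FALSE)
  if (any(tb == 0)) tb <- tb + 0.5
  or <- (tb["a"] * tb["d"]) / (tb["b"] * tb["c"])
  se <- sqrt(sum(1 / tb))
  list(odds_ratio = unname(or),
       ci_low = unname(exp(log(or) - z * se)),
       ci_high = unname(exp(log(or) + z * se)))
}

.empty_enrichment_row <- function(experiment_id, direction, library_name) {
  data.frame(experiment_id = experiment_id, direction = direction,
             library = library_name, a = NA_integer_, b = NA_integer_,
             c = NA_integer_, d = NA_integer_, odds_ratio = NA_real_,
             ci_low = NA_real_, ci_high = NA_real_, chi2 = NA_real_,
             p_value = NA_real_, perm_p = NA_real_, q_value = NA_real_,
             degenerate = TRUE, stringsAsFactors = FALSE)
}

#' Enrichment analysis of one experiment against the three L1 libraries
#'
#' Crosses the gene-level regulation calls of one knockdown experiment with
#' each library (`all`, `sense`, `antisense`) in each direction (`down`,
#' `up`), yielding exactly six rows with counts, odds ratio, Woolf 95% CI,
#' chi-squared statistic and p-value. Rows whose table has a degenerate
#' margin are emitted with `degenerate = TRUE` and `NA` statistics rather
#' than dropped. Permutation p-values and q-values are attached later by
#' [attach_permutation_p()] and [attach_qvalues()].
#'
#' @param calls Gene-level regulation table.
#' @param libraries Named list of [l1_library] objects with elements `all`,
#'   `sense`, `antisense` (as from [build_libraries()]).
#' @param experiment_id Identifier for the experiment; defaults to the
#'   `experiment_id` attribute of `calls`.
#' @return Data frame with one row per direction x library.
#' @export
analyze_experiment <- function(calls, libraries, experiment_id = NULL) {
  stopifnot(all(c("all", "sense", "antisense") %in% names(libraries)))
  if (is.null(experiment_id))
    experiment_id <- attr(calls, "experiment_id") %||% "experiment"
  rows <- list()
  for (direction in c("down", "up")) {
    for (lib_name in c("all", "sense", "antisense")) {
      lib <- libraries[[lib_name]]
      row <- tryCatch({
        tb <- build_contingency(calls, direction, lib)
        ct <- chi_squared_test(tb)
        or <- odds_ratio_ci(tb)
        data.frame(experiment_id = experiment_id, direction = direction,
                   library = lib_name, a = tb[["a"]], b = tb[["b"]],
                   c = tb[["c"]], d = tb[["d"]],
                   odds_ratio = or$odds_ratio, ci_low = or$ci_low,
                   ci_high = or$ci_high, chi2 = ct$chi2,
                   p_value = ct$p_value, perm_p = NA_real_,
                   q_value = NA_real_, degenerate = FALSE,
                   stringsAsFactors = FALSE)
      }, error = function(e) {
        row <- .empty_enrichment_row(experiment_id, direction, lib_name)
        tb <- tryCatch(build_contingency(calls, direction, lib),
                       error = function(e2) NULL)
        if (!is.null(tb)) row[, c("a", "b", "c", "d")] <- as.list(tb)
        row
      })
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Write enrichment results as TSV
#'
#' @param results Enrichment result table.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_enrichment_table <- function(results, file) {
  out <- results
  for (col in c("p_value", "perm_p", "q_value"))
    if (col %in% names(out)) out[[col]] <- .format_p(out[[col]])
  utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

# "." decimal, scientific notation below 1e-4
.format_p <- function(p) {
  ifelse(is.na(p), "NA",
         ifelse(p != 0 & p < 1e-4, sprintf("%.6e", p), sprintf("%.6f", p)))
}
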