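# End-to-end orchestration: read inputs, call regulation, collapse, enrich,
# permute, correct, classify, report.

#' Configuration for a screening run
#'
#' One run screens one or more knockdown experiments against a common set of
#' L1 host-gene libraries. Experiments are given as a manifest data frame
#' with one row per experiment and columns `experiment_id`, `series_matrix`,
#' `platform`, `template` (file paths); q-values are estimated jointly
#' across all experiments of the run, mirroring a screen corrected as one
#' family of tests.
#'
#' @param experiments Manifest data frame (see above), or a named list/vector
#'   with entries `series_matrix`, `platform`, `template` for a single
#'   experiment.
#' @param library_all,library_sense,library_antisense Paths to the three
#'   gene-list files.
#' @param alpha Per-gene significance level for regulation calls.
#' @param n_replicates Label shuffles per enrichment row.
#' @param q_threshold Significance threshold on q-values for classification.
#' @param lambda pi0 tuning grid (see [estimate_pi0_bootstrap()]).
#' @param n_boot Bootstrap resamples for pi0.
#' @param seed Integer seed governing permutations and the pi0 bootstrap.
#' @param out_dir Report directory.
#' @param probe_column,symbol_column,symbol_separator Platform annotation
#'   parsing options (see [read_platform_annotation()]).
#' @param plus_one Use the (r+1)/(n+1) permutation p-value estimator.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(experiments, library_all, library_sense,
                       library_antisense, alpha = 0.01,
                       n_replicates = 100000L, q_threshold = 0.05,
                       lambda = seq(0, 0.90, by = 0.05), n_boot = 100L,
                       seed = 1L, out_dir = "l1screen_results",
                       probe_column = "ID", symbol_column = "Gene Symbol",
                       symbol_separator = "///", plus_one = FALSE) {
  if (!is.data.frame(experiments)) {
    experiments <- as.list(experiments)
    experiments <- data.frame(
      experiment_id = experiments$experiment_id %||% "experiment",
      series_matrix = experiments$series_matrix,
      platform = experiments$platform,
      template = experiments$template, stringsAsFactors = FALSE)
  }
  need <- c("experiment_id", "series_matrix", "platform", "template")
  miss <- setdiff(need, names(experiments))
  if (length(miss))
    stop("experiment manifest is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  for (thr in c(alpha = alpha, q_threshold = q_threshold)) {
    if (!is.numeric(thr) || thr <= 0 || thr >= 1)
      stop("thresholds alpha and q_threshold must lie in (0, 1)",
           call. = FALSE)
  }
  if (as.integer(n_replicates) < 1L)
    stop("n_replicates must be at least 1", call. = FALSE)
  cfg <- list(experiments = experiments, library_all = library_all,
              library_sense = library_sense,
              library_antisense = library_antisense, alpha = alpha,
              n_replicates = as.integer(n_replicates),
              q_threshold = q_threshold, lambda = lambda,
              n_boot = as.integer(n_boot), seed = as.integer(seed),
              out_dir = out_dir, probe_column = probe_column,
              symbol_column = symbol_column,
              symbol_separator = symbol_separator, plus_one = plus_one)
  structure(cfg, class = "run_config")
}

#' Run the full screening pipeline
#'
#' For every experiment in the manifest: parse the series matrix, platform
#' annotation and template; call probe-level regulation at `alpha`; collapse
#' to genes by the minimum-p representative; build the 2x2 tables against
#' the three libraries and compute OR/CI/chi-squared; attach permutation
#' p-values. Then estimate pi0 and q-values jointly over all rows, classify
#' every experiment, and write the report. Per-stage counts are logged as
#' `key=value` messages.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `results` (enrichment table),
#'   `classification`, `pi0` and `paths` (report files).
#' @export
run_screen <- function(config) {
  stopifnot(inherits(config, "run_config"))
  libraries <- list(
    all = read_gene_list(config$library_all, "all"),
    sense = read_gene_list(config$library_sense, "sense"),
    antisense = read_gene_list(config$library_antisense, "antisense"))
  for (lib in libraries) {
    if (length(lib$genes) == 0L)
      stop("library '", lib$name, "' is empty", call. = FALSE)
  }
  set.seed(config$seed)

  all_results <- list()
  for (i in seq_len(nrow(config$experiments))) {
    ex <- config$experiments[i, ]
    values <- read_series_matrix(ex$series_matrix)
    probe_map <- read_platform_annotation(ex$platform,
                                          probe_column = config$probe_column,
                                          symbol_column = config$symbol_column,
                                          symbol_separator = config$symbol_separator)
    template <- read_sample_template(ex$template,
                                     experiment_id = ex$experiment_id)
    probe_calls <- call_regulation(values, template, alpha = config$alpha)
    calls <- collapse_to_genes(probe_calls, probe_map)
    message(sprintf("stage=regulation experiment=%s probes=%d genes=%d untestable=%d",
                    ex$experiment_id, nrow(probe_calls), nrow(calls),
                    sum(calls$call == "untestable")))
    res <- analyze_experiment(calls, libraries,
                              experiment_id = ex$experiment_id)
    res <- attach_permutation_p(res, calls, libraries,
                                n_replicates = config$n_replicates,
                                seed = NULL, plus_one = config$plus_one)
    message(sprintf("stage=enrichment experiment=%s rows=%d degenerate=%d",
                    ex$experiment_id, nrow(res), sum(res$degenerate)))
    all_results[[i]] <- res
  }
  results <- do.call(rbind, all_results)

  results <- attach_qvalues(results, lambda = config$lambda,
                            n_boot = config$n_boot, seed = NULL)
  pi0 <- attr(results, "pi0")
  message(sprintf("stage=fdr tests=%d pi0=%.4f",
                  sum(!is.na(results$perm_p)), pi0))

  classification <- classify_all(results, config$q_threshold)
  paths <- write_report(results, classification, config$out_dir,
                        run_info = list(seed = config$seed,
                                        alpha = config$alpha,
                                        n_replicates = config$n_replicates,
                                        pi0 = signif(pi0, 6)),
                        q_threshold = config$q_threshold)
  message(sprintf("stage=report dir=%s experiments=%d", config$out_dir,
                  nrow(classification)))
  invisible(list(results = results, classification = classification,
                 pi0 = pi0, paths = paths))
}

#' Generate and write a synthetic experiment bundle
#'
#' Thin wrapper over [generate_experiment()] and [write_experiment()].
#'
#' @param config A [synthetic_config()].
#' @param out_dir Output directory.
#' @return Named character vector of file paths, invisibly.
#' @export
simulate_experiment <- function(config = synthetic_config(), out_dir) {
  sim <- generate_experiment(config)
  write_experiment(sim, out_dir)
}
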