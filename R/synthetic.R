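# Synthetic knockdown experiments with planted ground truth, in the same
# file dialects the readers consume. Regulation is planted at the truth
# level (membership-dependent regulation odds) and expressed as mean shifts,
# so association (what enrichment measures) and detectability (what the
# t-test measures) can be varied independently.

#' Configuration for a synthetic knockdown experiment
#'
#' Defaults emulate the regime of a genome-wide expression array screened at
#' significance level 0.01: ~20,000 genes of which ~6.6% carry a full-length
#' intragenic L1, three control vs three experimental samples, log2-scale
#' baselines around 8, and a planted regulation odds ratio of 1 (null).
#'
#' The planted model: every gene is regulated with probability
#' `p_reg_background` if it carries no L1, and with the probability whose
#' odds are `target_or` times the background odds if it does. Regulated
#' genes are up or down with equal probability and their experimental means
#' shift by `+/- effect_size`.
#'
#' @param n_genes Number of genes (>= 100).
#' @param l1_fraction Fraction of genes carrying an intragenic L1.
#' @param probes_per_gene Probability weights for 1, 2, 3 probes per gene.
#' @param n_control,n_experimental Samples per group.
#' @param baseline_mean,baseline_sd Normal distribution of per-gene baseline
#'   expression (log2 scale).
#' @param noise_sd Per-sample measurement noise SD (log2 scale).
#' @param p_reg_background Regulation probability of a non-L1 gene.
#' @param target_or Planted odds ratio of regulation, L1 vs non-L1 genes.
#' @param effect_size Absolute log2 mean shift of regulated genes.
#' @param missing_rate Probability that a measurement is missing.
#' @param experiment_id Identifier used in the template and outputs.
#' @param seed Optional integer seed; generation is deterministic given it.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 20000L, l1_fraction = 0.066,
                             probes_per_gene = c(0.7, 0.2, 0.1),
                             n_control = 3L, n_experimental = 3L,
                             baseline_mean = 8, baseline_sd = 2,
                             noise_sd = 0.25, p_reg_background = 0.01,
                             target_or = 1.0, effect_size = 1.0,
                             missing_rate = 0.001,
                             experiment_id = "synthetic_knockdown",
                             seed = NULL) {
  cfg <- list(n_genes = as.integer(n_genes), l1_fraction = l1_fraction,
              probes_per_gene = probes_per_gene,
              n_control = as.integer(n_control),
              n_experimental = as.integer(n_experimental),
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              noise_sd = noise_sd, p_reg_background = p_reg_background,
              target_or = target_or, effect_size = effect_size,
              missing_rate = missing_rate, experiment_id = experiment_id,
              seed = seed)
  probs <- c(cfg$l1_fraction, cfg$p_reg_background, cfg$missing_rate,
             cfg$probes_per_gene)
  if (anyNA(probs) || any(probs < 0 | probs > 1))
    stop("synthetic_config: probabilities must lie in [0, 1]", call. = FALSE)
  if (abs(sum(cfg$probes_per_gene) - 1) > 1e-8)
    stop("synthetic_config: probes_per_gene weights must sum to 1",
         call. = FALSE)
  if (is.na(cfg$n_genes) || cfg$n_genes < 100L)
    stop("synthetic_config: n_genes must be at least 100", call. = FALSE)
  if (!is.numeric(cfg$target_or) || cfg$target_or <= 0)
    stop("synthetic_config: target_or must be positive", call. = FALSE)
  if (cfg$effect_size < 0)
    stop("synthetic_config: effect_size must be non-negative", call. = FALSE)
  if (cfg$noise_sd <= 0)
    stop("synthetic_config: noise_sd must be positive", call. = FALSE)
  if (cfg$n_control < 1L || cfg$n_experimental < 1L)
    stop("synthetic_config: need at least one sample per group",
         call. = FALSE)
  structure(cfg, class = "synthetic_config")
}

#' Background regulation rate matching a target regulated-gene count
#'
#' Solves for the non-L1 regulation probability `p0` such that the expected
#' number of regulated genes equals `n_regulated`, given the planted odds
#' ratio (`odds(p1) = target_or * odds(p0)` for L1 genes).
#'
#' @param n_genes Universe size.
#' @param l1_fraction Fraction of genes carrying an L1.
#' @param target_or Planted odds ratio.
#' @param n_regulated Desired expected count of regulated genes.
#' @return The background probability `p0`.
#' @export
tune_background_rate <- function(n_genes, l1_fraction, target_or,
                                 n_regulated) {
  n_l1 <- round(n_genes * l1_fraction)
  f <- function(p0) {
    odds1 <- target_or * p0 / (1 - p0)
    p1 <- odds1 / (1 + odds1)
    n_l1 * p1 + (n_genes - n_l1) * p0 - n_regulated
  }
  stats::uniroot(f, c(1e-9, 0.999), tol = 1e-12)$root
}

#' Generate a synthetic knockdown experiment with planted truth
#'
#' Draws per-gene L1 membership, strand, regulation status and direction
#' from the planted model of [synthetic_config()], then emits probe-level
#' expression values (gene baseline + effect in the experimental group +
#' noise, rounded to 4 decimals as deposited expression tables are) and the
#' companion artifacts: platform probe-to-symbol map, control/experimental
#' template, the three L1 host-gene libraries, and the per-gene truth table.
#'
#' @param config A [synthetic_config()].
#' @return List of class `l1_sim` with elements `expression` (probe x sample
#'   matrix with `NA` missing values), `platform`, `template`, `libraries`
#'   (list of three [l1_library]), `truth` (data frame: `gene`, `has_l1`,
#'   `strand`, `true_direction`, `effect`) and `config`.
#' @export
generate_experiment <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_genes
  genes <- sprintf("SYNG%05d", seq_len(n))

  n_l1 <- round(n * config$l1_fraction)
  has_l1 <- rep(FALSE, n)
  has_l1[sample.int(n, n_l1)] <- TRUE
  strand <- rep("none", n)
  strand[has_l1] <- sample(c("sense", "antisense"), n_l1, replace = TRUE)

  p0 <- config$p_reg_background
  odds1 <- config$target_or * p0 / (1 - p0)
  p1 <- odds1 / (1 + odds1)
  regulated <- stats::rbinom(n, 1L, ifelse(has_l1, p1, p0)) == 1L
  direction <- rep("none", n)
  direction[regulated] <- sample(c("up", "down"), sum(regulated),
                                 replace = TRUE)
  effect <- ifelse(direction == "up", config$effect_size,
                   ifelse(direction == "down", -config$effect_size, 0))
  truth <- data.frame(gene = genes, has_l1 = has_l1, strand = strand,
                      true_direction = direction, effect = effect,
                      stringsAsFactors = FALSE)

  k <- sample.int(length(config$probes_per_gene), n, replace = TRUE,
                  prob = config$probes_per_gene)
  gene_of_probe <- rep(seq_len(n), k)
  m <- length(gene_of_probe)
  probes <- sprintf("SYNP%06d", seq_len(m))
  platform <- data.frame(ID = probes, `Gene Symbol` = genes[gene_of_probe],
                         check.names = FALSE, stringsAsFactors = FALSE)

  nc <- config$n_control; ne <- config$n_experimental
  samples <- c(sprintf("CTRL_%d", seq_len(nc)), sprintf("KD_%d", seq_len(ne)))
  base <- stats::rnorm(n, config$baseline_mean, config$baseline_sd)
  mu <- matrix(rep(base[gene_of_probe], nc + ne), nrow = m)
  mu[, nc + seq_len(ne)] <- mu[, nc + seq_len(ne)] + effect[gene_of_probe]
  values <- mu + stats::rnorm(m * (nc + ne), 0, config$noise_sd)
  values <- round(values, 4)  # deposited-table precision; exact round-trips
  if (config$missing_rate > 0) {
    values[stats::runif(length(values)) < config$missing_rate] <- NA_real_
  }
  dimnames(values) <- list(probes, samples)

  template <- data.frame(sample_id = samples,
                         role = rep(c("control", "experimental"), c(nc, ne)),
                         stringsAsFactors = FALSE)
  attr(template, "experiment_id") <- config$experiment_id

  libraries <- list(
    all = l1_library(genes[has_l1], "all"),
    sense = l1_library(genes[strand == "sense"], "sense"),
    antisense = l1_library(genes[strand == "antisense"], "antisense"))

  structure(list(expression = values, platform = platform,
                 template = template, libraries = libraries, truth = truth,
                 config = config),
            class = "l1_sim")
}

#' @export
print.l1_sim <- function(x, ...) {
  cat("synthetic knockdown experiment '", x$config$experiment_id, "'\n",
      "  ", nrow(x$expression), " probes x ", ncol(x$expression),
      " samples; ", x$config$n_genes, " genes (",
      sum(x$truth$has_l1), " with L1, ",
      sum(x$truth$true_direction != "none"), " regulated)\n", sep = "")
  invisible(x)
}

#' Write a synthetic experiment in the pipeline's input dialects
#'
#' Emits `series_matrix.txt` (GEO series-matrix dialect, missing values as
#' `null`), `platform.tsv`, `template.tsv`, `library_all.txt`,
#' `library_sense.txt`, `library_antisense.txt` and `truth.tsv` into `dir`.
#' All files parse back through the package readers.
#'
#' @param sim An `l1_sim` from [generate_experiment()].
#' @param dir Output directory, created if absent.
#' @return Named character vector of paths, invisibly.
#' @export
write_experiment <- function(sim, dir) {
  stopifnot(inherits(sim, "l1_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(series_matrix = file.path(dir, "series_matrix.txt"),
             platform = file.path(dir, "platform.tsv"),
             template = file.path(dir, "template.tsv"),
             library_all = file.path(dir, "library_all.txt"),
             library_sense = file.path(dir, "library_sense.txt"),
             library_antisense = file.path(dir, "library_antisense.txt"),
             truth = file.path(dir, "truth.tsv"))

  v <- sim$expression
  body <- apply(v, 1L, function(row) {
    s <- sprintf("%.4f", row)
    s[is.na(row)] <- "null"
    paste(s, collapse = "\t")
  })
  lines <- c(sprintf("!Series_title\t\"%s\"", sim$config$experiment_id),
             "!Series_platform_id\t\"SYNPLATFORM1\"",
             "!series_matrix_table_begin",
             paste(c("\"ID_REF\"", sprintf("\"%s\"", colnames(v))),
                   collapse = "\t"),
             paste(sprintf("\"%s\"", rownames(v)), body, sep = "\t"),
             "!series_matrix_table_end")
  writeLines(lines, paths[["series_matrix"]])

  utils::write.table(sim$platform, paths[["platform"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$template, paths[["template"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_gene_list(sim$libraries$all, paths[["library_all"]])
  write_gene_list(sim$libraries$sense, paths[["library_sense"]])
  write_gene_list(sim$libraries$antisense, paths[["library_antisense"]])
  utils::write.table(sim$truth, paths[["truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Generate a p-value mixture with a known null proportion
#'
#' `floor(pi0 * m)` p-values are Uniform(0, 1) (true nulls) and the
#' remainder are Beta(`beta_shape`, 1) (alternatives concentrated near 0);
#' the vector is shuffled. Used to exercise the pi0/q-value stage at known
#' ground truth.
#'
#' @param m Number of p-values (>= 1).
#' @param pi0 True null proportion in \[0, 1\].
#' @param beta_shape Beta shape parameter in (0, 1); smaller values push
#'   alternative p-values closer to 0.
#' @param seed Optional integer seed.
#' @return Numeric vector of `m` p-values.
#' @export
generate_pvalue_mixture <- function(m, pi0, beta_shape = 0.1, seed = NULL) {
  m <- as.integer(m)
  if (is.na(m) || m < 1L)
    stop("m must be a positive integer", call. = FALSE)
  if (!is.numeric(pi0) || pi0 < 0 || pi0 > 1)
    stop("pi0 must lie in [0, 1]", call. = FALSE)
  if (!is.numeric(beta_shape) || beta_shape <= 0 || beta_shape >= 1)
    stop("beta_shape must lie in (0, 1)", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n0 <- floor(pi0 * m)
  p <- c(stats::runif(n0), stats::rbeta(m - n0, beta_shape, 1))
  sample(p)
}
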