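# Final classification of experiments by direction/side of significant
# associations and by strand of the involved L1 libraries; report writing.

#' The seven direction/OR group labels
#'
#' Possible values of the experiment-level group assigned by
#' [classify_experiment()].
#' @export
GROUP_LABELS <- c("Down and Up < 1", "Down and Up > 1", "Down < 1",
                  "Down > 1", "Up < 1", "Up > 1", "non-significant")

#' The four strand-association categories
#'
#' Possible values returned by [strand_category()] for experiments with at
#' least one significant library-level result.
#' @export
STRAND_CATEGORIES <- c("sense+antisense", "sense-only", "antisense-only",
                       "all-only")

#' Classify one experiment into the seven direction/OR groups
#'
#' Uses the experiment's two `all`-library rows. A direction is significant
#' when its q-value is below `q_threshold`; each significant direction is
#' annotated by whether its odds ratio lies above or below 1. When both
#' directions are significant on the same side the compound labels
#' `"Down and Up > 1"` / `"Down and Up < 1"` apply; mixed sides collapse
#' onto the label of the OR > 1 direction (downregulation of library genes
#' with OR > 1 is the same event as their "upregulation" with OR < 1, so a
#' significant down/OR > 1 paired with up/OR < 1 is reported as
#' `"Down > 1"`, and symmetrically for `"Up > 1"`). No significant
#' direction gives `"non-significant"`.
#'
#' @param results Enrichment rows of one experiment with `q_value` attached;
#'   only `library == "all"` rows are used.
#' @param q_threshold Significance threshold on the q-value.
#' @return One of the seven group labels (see `GROUP_LABELS`).
#' @export
classify_experiment <- function(results, q_threshold = 0.05) {
  rows <- results[results$library == "all", , drop = FALSE]
  if (!all(c("down", "up") %in% rows$direction))
    stop("classification needs both direction rows for the 'all' library",
         call. = FALSE)
  get <- function(d) rows[match(d, rows$direction), , drop = FALSE]
  down <- get("down"); up <- get("up")
  sig <- function(r) !is.na(r$q_value) && r$q_value < q_threshold
  side <- function(r) {
    if (is.na(r$odds_ratio))
      stop("significant row without an odds ratio", call. = FALSE)
    if (r$odds_ratio == 1)
      stop("contradictory classification: q < threshold with OR exactly 1",
           call. = FALSE)
    if (r$odds_ratio > 1) ">" else "<"
  }
  ds <- sig(down); us <- sig(up)
  if (!ds && !us) return("non-significant")
  if (ds && us) {
    sd <- side(down); su <- side(up)
    if (sd == ">" && su == ">") return("Down and Up > 1")
    if (sd == "<" && su == "<") return("Down and Up < 1")
    # mixed sides: the OR > 1 direction carries the label (its complement
    # statement is the same association read from the other margin)
    return(if (sd == ">") "Down > 1" else "Up > 1")
  }
  if (ds) return(paste("Down", side(down), "1"))
  paste("Up", side(up), "1")
}

#' Strand category of one experiment
#'
#' A library is significant when any of its direction rows has
#' `q < q_threshold`. Categories: `"sense+antisense"` when both strand
#' libraries are significant, `"sense-only"` / `"antisense-only"` when one
#' is, and `"all-only"` when neither strand library is significant but the
#' combined `all` library is. When no library is significant the category
#' is undefined and `NA` is returned.
#'
#' @param results Enrichment rows of one experiment (all three libraries)
#'   with `q_value` attached.
#' @param q_threshold Significance threshold on the q-value.
#' @return One of `STRAND_CATEGORIES`, or `NA_character_`.
#' @export
strand_category <- function(results, q_threshold = 0.05) {
  sig_lib <- function(lib) {
    q <- results$q_value[results$library == lib]
    any(!is.na(q) & q < q_threshold)
  }
  s <- sig_lib("sense"); a <- sig_lib("antisense"); al <- sig_lib("all")
  if (s && a) return("sense+antisense")
  if (s) return("sense-only")
  if (a) return("antisense-only")
  if (al) return("all-only")
  NA_character_
}

#' Classify every experiment in an enrichment table
#'
#' @param results Enrichment table with `q_value` attached, possibly many
#'   experiments.
#' @param q_threshold Significance threshold on the q-value.
#' @return Data frame with columns `experiment_id`, `group`,
#'   `strand_category`.
#' @export
classify_all <- function(results, q_threshold = 0.05) {
  ids <- unique(results$experiment_id)
  out <- data.frame(experiment_id = ids, group = NA_character_,
                    strand_category = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(ids)) {
    rows <- results[results$experiment_id == ids[i], , drop = FALSE]
    out$group[i] <- classify_experiment(rows, q_threshold)
    out$strand_category[i] <- strand_category(rows, q_threshold)
  }
  out
}

#' Write the final report files
#'
#' Writes three files into `dir`: `enrichment.tsv` (every enrichment row,
#' with p/q-values below 1e-4 in scientific notation),
#' `classification.tsv` (one row per experiment) and `run_info.txt`
#' (machine-parsable `key=value` lines: thresholds, seeds, package version
#' and the count of experiments per group).
#'
#' @param results Enrichment table with q-values attached.
#' @param classification Output of [classify_all()]; recomputed when `NULL`.
#' @param dir Output directory, created if absent.
#' @param run_info Named list of extra `key=value` entries (e.g. seed,
#'   n_replicates).
#' @param q_threshold Threshold used when recomputing the classification.
#' @return Named character vector of the three paths, invisibly.
#' @export
write_report <- function(results, classification = NULL, dir,
                         run_info = list(), q_threshold = 0.05) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(dir))
      stop("cannot create output directory: ", dir, call. = FALSE)
  }
  if (is.null(classification))
    classification <- classify_all(results, q_threshold)

  master <- file.path(dir, "enrichment.tsv")
  write_enrichment_table(results, master)

  cls <- file.path(dir, "classification.tsv")
  utils::write.table(classification, cls, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  counts <- table(factor(classification$group, levels = GROUP_LABELS))
  info <- c(list(package_version = as.character(utils::packageVersion("l1screen")),
                 n_experiments = nrow(classification),
                 n_enrichment_rows = nrow(results),
                 q_threshold = q_threshold),
            run_info,
            stats::setNames(as.list(as.integer(counts)),
                            paste0("group_count[", names(counts), "]")))
  meta <- file.path(dir, "run_info.txt")
  writeLines(paste0(names(info), "=", vapply(info, as.character, "")), meta)

  invisible(c(enrichment = master, classification = cls, run_info = meta))
}
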