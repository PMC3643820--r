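# Readers for the GEO series-matrix dialect, sample templates and platform
# probe annotation, plus the probe -> gene collapse applied after testing.

MISSING_TOKENS <- c("", "null", "na", "nan")

.read_lines <- function(file) {
  if (inherits(file, "connection")) return(readLines(file, warn = FALSE))
  stopifnot(is.character(file), length(file) == 1L)
  if (!file.exists(file)) stop("file not found: ", file, call. = FALSE)
  con <- gzfile(file, "rt")  # reads plain text and gzip alike
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

.unquote <- function(x) {
  x <- trimws(x)
  q <- nchar(x) >= 2L & startsWith(x, "\"") & endsWith(x, "\"")
  x[q] <- substr(x[q], 2L, nchar(x[q]) - 1L)
  x
}

#' Read an expression matrix from a GEO-style series-matrix file
#'
#' Parses the `!series_matrix_table_begin` ... `!series_matrix_table_end`
#' block of a series-matrix file. The first row of the block is the sample-ID
#' header (its first field, usually `ID_REF`, is ignored); the first column
#' holds probe identifiers. Metadata lines outside the block (prefixed `!`)
#' are ignored. Quoted fields are unquoted. The tokens `""`, `"null"`,
#' `"NA"` and `"NaN"` (case-insensitive), and any field that does not parse
#' as a number, become missing values.
#'
#' Values are used exactly as deposited; no renormalisation or log detection
#' is attempted.
#'
#' @param file Path to a series-matrix file (plain or gzip-compressed) or a
#'   readable connection.
#' @return A numeric matrix, rows = probes (rownames), columns = samples
#'   (colnames); missing entries are `NA`.
#' @examples
#' lines <- c("!Series_title \"demo\"",
#'            "!series_matrix_table_begin",
#'            "\"ID_REF\"\t\"S1\"\t\"S2\"",
#'            "\"P1\"\t1.5\t2.5",
#'            "\"P2\"\tnull\t3.0",
#'            "!series_matrix_table_end")
#' m <- read_series_matrix(textConnection(lines))
#' sum(is.na(m))  # 1
#' @export
read_series_matrix <- function(file) {
  lines <- .read_lines(file)
  beg <- grep("^!series_matrix_table_begin", lines, ignore.case = TRUE)
  end <- grep("^!series_matrix_table_end", lines, ignore.case = TRUE)
  if (length(beg) == 0L)
    stop("series-matrix format error: missing '!series_matrix_table_begin' marker",
         call. = FALSE)
  if (length(end) == 0L)
    stop("series-matrix format error: missing '!series_matrix_table_end' marker",
         call. = FALSE)
  beg <- beg[1L]; end <- end[end > beg][1L]
  if (is.na(end))
    stop("series-matrix format error: missing '!series_matrix_table_end' marker",
         call. = FALSE)
  block <- lines[(beg + 1L):(end - 1L)]
  block <- block[nzchar(trimws(block))]
  if (length(block) < 2L)
    stop("series-matrix format error: empty data block", call. = FALSE)

  header <- .unquote(strsplit(block[1L], "\t", fixed = TRUE)[[1L]])
  sample_ids <- header[-1L]
  dup <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup))
    stop("duplicate sample ID in series matrix: ", paste(dup, collapse = ", "),
         call. = FALSE)

  rows <- strsplit(block[-1L], "\t", fixed = TRUE)
  probe_ids <- .unquote(vapply(rows, `[`, "", 1L))
  dup <- unique(probe_ids[duplicated(probe_ids)])
  if (length(dup))
    stop("duplicate probe ID in series matrix: ", paste(dup, collapse = ", "),
         call. = FALSE)

  parse_row <- function(fields) {
    v <- .unquote(fields[-1L])
    length(v) <- length(sample_ids)      # ragged short rows pad with NA
    v[tolower(v) %in% MISSING_TOKENS] <- NA_character_
    suppressWarnings(as.numeric(v))      # unparsable numerics -> NA
  }
  values <- t(vapply(rows, parse_row, numeric(length(sample_ids))))
  values[!is.finite(values)] <- NA_real_
  dimnames(values) <- list(probe_ids, sample_ids)
  values
}

#' Read a control/experimental sample template
#'
#' A template assigns every sample of one knockdown experiment to the
#' `control` group (scramble/mock/reporter constructs) or the `experimental`
#' group (the targeting siRNA/shRNA). The file is a delimited table (tab or
#' comma, sniffed from the header) with columns `sample_id` and `role`; role
#' spellings are matched case-insensitively.
#'
#' @param file Path (plain or gzip) or connection.
#' @param experiment_id Optional experiment identifier stored as an
#'   attribute; defaults to the file name without extension.
#' @return A data frame with columns `sample_id` and `role`
#'   (`"control"`/`"experimental"`) and attribute `experiment_id`.
#' @export
read_sample_template <- function(file, experiment_id = NULL) {
  lines <- .read_lines(file)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) < 2L)
    stop("sample template has no data rows", call. = FALSE)
  sep <- if (grepl("\t", lines[1L], fixed = TRUE)) "\t" else ","
  tab <- utils::read.table(text = lines, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, quote = "\"",
                           check.names = FALSE)
  names(tab) <- tolower(trimws(names(tab)))
  miss <- setdiff(c("sample_id", "role"), names(tab))
  if (length(miss))
    stop("sample template is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  out <- data.frame(sample_id = trimws(as.character(tab$sample_id)),
                    role = tolower(trimws(as.character(tab$role))),
                    stringsAsFactors = FALSE)
  bad <- setdiff(unique(out$role), c("control", "experimental"))
  if (length(bad))
    stop("unknown role token(s) in sample template: ",
         paste(bad, collapse = ", "), call. = FALSE)
  dup <- unique(out$sample_id[duplicated(out$sample_id)])
  if (length(dup))
    stop("sample assigned more than one role: ", paste(dup, collapse = ", "),
         call. = FALSE)
  if (!any(out$role == "control"))
    stop("no control samples in template", call. = FALSE)
  if (!any(out$role == "experimental"))
    stop("no experimental samples in template", call. = FALSE)
  if (is.null(experiment_id))
    experiment_id <- if (is.character(file))
      sub("\\.[^.]*$", "", basename(file)) else "experiment"
  attr(out, "experiment_id") <- experiment_id
  out
}

#' Read a platform probe-to-gene annotation table
#'
#' Reads a tab-delimited platform annotation (header required, `#` comment
#' lines skipped) and returns the probe-to-symbol map in long format. The
#' symbol field is split on `symbol_separator` (GEO platforms conventionally
#' use `"///"` for multi-gene probes); symbols are whitespace-trimmed and
#' uppercased, and empty symbols are dropped, so probes whose symbol field is
#' blank map to no gene.
#'
#' @param file Path (plain or gzip) or connection.
#' @param probe_column,symbol_column Names of the probe-ID and gene-symbol
#'   columns in the header.
#' @param symbol_separator Separator between multiple symbols in one field.
#' @return A data frame with columns `probe_id` and `symbol`, one row per
#'   (probe, symbol) pair.
#' @export
read_platform_annotation <- function(file, probe_column = "ID",
                                     symbol_column = "Gene Symbol",
                                     symbol_separator = "///") {
  lines <- .read_lines(file)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  tab <- utils::read.table(text = lines, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, quote = "\"",
                           check.names = FALSE, comment.char = "")
  for (col in c(probe_column, symbol_column)) {
    if (!col %in% names(tab))
      stop("platform annotation has no column '", col, "'; available: ",
           paste(names(tab), collapse = ", "), call. = FALSE)
  }
  probes <- trimws(as.character(tab[[probe_column]]))
  syms <- strsplit(as.character(tab[[symbol_column]]), symbol_separator,
                   fixed = TRUE)
  n <- lengths(syms)
  out <- data.frame(probe_id = rep(probes, n),
                    symbol = toupper(trimws(unlist(syms, use.names = FALSE))),
                    stringsAsFactors = FALSE)
  out <- out[!is.na(out$symbol) & nzchar(out$symbol) & out$symbol != "NA", ,
             drop = FALSE]
  rownames(out) <- NULL
  unique(out)
}

#' Collapse probe-level regulation results to gene level
#'
#' Gene-level regulation is represented by the mapped probe with the smallest
#' t-test p-value (testable probes are preferred over untestable ones; ties
#' are broken by the lexicographically smallest probe ID). The gene inherits
#' that probe's p-value, statistics and call, so the gene p-value always
#' equals the minimum over its testable probes. Genes whose probes are all
#' untestable stay untestable. Probes absent from the map are dropped with a
#' message.
#'
#' @param probe_results A regulation table as returned by [call_regulation()]
#'   on a probe-level matrix (column `id` holds probe IDs).
#' @param probe_map Long-format map from [read_platform_annotation()].
#' @return A regulation table keyed by gene: columns `gene`, `probe`
#'   (representative probe), `mean_control`, `mean_experimental`, `t`, `p`,
#'   `call`.
#' @export
collapse_to_genes <- function(probe_results, probe_map) {
  stopifnot(is.data.frame(probe_results), "id" %in% names(probe_results),
            is.data.frame(probe_map),
            all(c("probe_id", "symbol") %in% names(probe_map)))
  n_unmapped <- sum(!probe_results$id %in% probe_map$probe_id)
  if (n_unmapped > 0L)
    message("collapse_to_genes: dropped ", n_unmapped, " unmapped probe(s)")
  m <- merge(probe_map, probe_results, by.x = "probe_id", by.y = "id")
  if (nrow(m) == 0L)
    return(data.frame(gene = character(), probe = character(),
                      mean_control = numeric(), mean_experimental = numeric(),
                      t = numeric(), p = numeric(), call = character(),
                      stringsAsFactors = FALSE))
  untestable <- m$call == "untestable"
  ord <- order(m$symbol, untestable, m$p, m$probe_id, na.last = TRUE)
  m <- m[ord, , drop = FALSE]
  rep_row <- m[!duplicated(m$symbol), , drop = FALSE]
  out <- data.frame(gene = rep_row$symbol, probe = rep_row$probe_id,
                    mean_control = rep_row$mean_control,
                    mean_experimental = rep_row$mean_experimental,
                    t = rep_row$t, p = rep_row$p, call = rep_row$call,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "experiment_id") <- attr(probe_results, "experiment_id")
  attr(out, "alpha") <- attr(probe_results, "alpha")
  out
}
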