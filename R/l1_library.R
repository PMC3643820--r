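# L1 host-gene libraries: filtering full-length elements, strand-aware
# containment within gene bodies, and plain gene-list I/O.

#' Construct an L1 host-gene library
#'
#' @param genes Character vector of gene symbols; uppercased and deduplicated.
#' @param name Library name, conventionally one of `"all"`, `"sense"`,
#'   `"antisense"`.
#' @return An object of class `l1_library`: a list with elements `name` and
#'   `genes` (sorted unique uppercase symbols).
#' @export
l1_library <- function(genes, name = "all") {
  genes <- toupper(trimws(as.character(genes)))
  genes <- sort(unique(genes[nzchar(genes)]))
  structure(list(name = name, genes = genes), class = "l1_library")
}

#' @export
print.l1_library <- function(x, ...) {
  cat("L1 host-gene library '", x$name, "': ", length(x$genes), " genes\n",
      sep = "")
  invisible(x)
}

#' Filter L1 records to full-length elements
#'
#' A full-length element is at least `min_length_bp` long (default 4,500 bp)
#' and carries a 5' UTR. Intervals are 0-based half-open, so the length of a
#' record is `end - start`.
#'
#' @param l1s Data frame with columns `chrom`, `start`, `end`, `strand`
#'   and `has_5utr` (logical).
#' @param min_length_bp Minimum element length in bp; the boundary value is
#'   kept (`>=` semantics).
#' @param require_5utr Keep only elements with an intact 5' UTR.
#' @return The filtered data frame, input order preserved.
#' @export
filter_full_length <- function(l1s, min_length_bp = 4500, require_5utr = TRUE) {
  .validate_intervals(l1s, "L1 records")
  if (!"has_5utr" %in% names(l1s))
    stop("L1 records need a logical 'has_5utr' column", call. = FALSE)
  keep <- (l1s$end - l1s$start) >= min_length_bp
  if (require_5utr) keep <- keep & as.logical(l1s$has_5utr)
  l1s[keep, , drop = FALSE]
}

.validate_intervals <- function(x, what) {
  need <- c("chrom", "start", "end", "strand")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop(what, " are missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(x$start >= x$end))
    stop(what, ": every interval must satisfy start < end (0-based half-open)",
         call. = FALSE)
  if (!all(x$strand %in% c("+", "-")))
    stop(what, ": strand must be '+' or '-'", call. = FALSE)
  invisible(x)
}

#' Build the three intragenic-L1 host-gene libraries
#'
#' An L1 element is intragenic to a gene when it lies on the same chromosome
#' and is fully contained within the gene body (`gene start <= L1 start` and
#' `L1 end <= gene end`, 0-based half-open); containment ignores strand.
#' Every host gene enters the `all` library; it additionally enters `sense`
#' when it hosts an L1 on its own strand and `antisense` when it hosts an L1
#' on the opposite strand, so a gene hosting both orientations appears in
#' both strand libraries.
#'
#' @param l1s Data frame of L1 elements (`chrom`, `start`, `end`, `strand`),
#'   typically pre-filtered with [filter_full_length()].
#' @param genes Data frame of gene bodies (`symbol`, `chrom`, `start`, `end`,
#'   `strand`).
#' @return Named list of three [l1_library] objects: `all`, `sense`,
#'   `antisense` (with `sense` and `antisense` subsets of `all`).
#' @export
build_libraries <- function(l1s, genes) {
  .validate_intervals(l1s, "L1 records")
  .validate_intervals(genes, "gene records")
  if (!"symbol" %in% names(genes) || any(!nzchar(trimws(genes$symbol))))
    stop("gene records need a non-empty 'symbol' column", call. = FALSE)

  # intervals are 0-based half-open; GRanges are 1-based closed
  gr_l1 <- GenomicRanges::GRanges(l1s$chrom,
                                  IRanges::IRanges(l1s$start + 1L, l1s$end))
  gr_gene <- GenomicRanges::GRanges(genes$chrom,
                                    IRanges::IRanges(genes$start + 1L,
                                                     genes$end))
  hits <- GenomicRanges::findOverlaps(gr_l1, gr_gene, type = "within",
                                      ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  host <- toupper(trimws(genes$symbol[si]))
  same_strand <- l1s$strand[qi] == genes$strand[si]
  if (length(host) == 0L)
    warning("no intragenic L1 elements found; libraries are empty")
  list(all = l1_library(host, "all"),
       sense = l1_library(host[same_strand], "sense"),
       antisense = l1_library(host[!same_strand], "antisense"))
}

#' Read a gene list into an L1 library
#'
#' One gene symbol per line; blank lines and `#` comments are skipped;
#' symbols are uppercased and deduplicated.
#'
#' @param file Path (plain or gzip) or connection.
#' @param name Library name for the result.
#' @return An [l1_library] object.
#' @export
read_gene_list <- function(file, name = "all") {
  lines <- trimws(.read_lines(file))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L)
    stop("gene list is empty after removing comments and blank lines",
         call. = FALSE)
  l1_library(lines, name)
}

#' Write an L1 library as a plain gene list
#'
#' @param library An [l1_library] object.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_gene_list <- function(library, file) {
  stopifnot(inherits(library, "l1_library"))
  writeLines(c(paste0("# L1 host-gene library: ", library$name),
               library$genes), con = file)
  invisible(file)
}

#' Read a BED-like interval table
#'
#' Tab-delimited with a header naming at least `chrom`, `start`, `end`,
#' `strand`; extra columns (for example `symbol` for genes or `has_5utr` for
#' L1 elements) are kept. Coordinates are 0-based half-open, as in BED.
#'
#' @param file Path (plain or gzip) or connection.
#' @return A data frame.
#' @export
read_interval_table <- function(file) {
  lines <- .read_lines(file)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  tab <- utils::read.table(text = lines, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, quote = "\"",
                           check.names = FALSE)
  if ("has_5utr" %in% names(tab)) tab$has_5utr <- as.logical(tab$has_5utr)
  .validate_intervals(tab, "intervals")
}
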