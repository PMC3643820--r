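series_lines <- function(header, rows, extra_meta = character()) {
  c("!Series_title\t\"demo\"", extra_meta,
    "!series_matrix_table_begin",
    paste(c("\"ID_REF\"", sprintf("\"%s\"", header)), collapse = "\t"),
    rows,
    "!series_matrix_table_end",
    "!Series_footer\t\"x\"")
}

test_that("series-matrix parsing handles missing tokens and quoting", {
  path <- write_series_lines(series_lines(
    c("S1", "S2", "S3", "S4"),
    c("\"P1\"\t1.0\t2.0\t3.0\t4.0",
      "\"P2\"\t5.5\tnull\t6.5\t7.5",
      "P3\t-1.25\t0\t1e-3\t2.5e2")))
  m <- read_series_matrix(path)
  expect_identical(dim(m), c(3L, 4L))
  expect_identical(rownames(m), c("P1", "P2", "P3"))
  expect_identical(colnames(m), c("S1", "S2", "S3", "S4"))
  expect_identical(sum(is.na(m)), 1L)
  expect_true(is.na(m["P2", "S2"]))
  expect_identical(m["P3", ], c(S1 = -1.25, S2 = 0, S3 = 1e-3, S4 = 250))
})

test_that("all case-insensitive missing tokens and junk become NA", {
  path <- write_series_lines(series_lines(
    c("S1", "S2", "S3", "S4", "S5"),
    "\"P1\"\tNA\tNaN\tNULL\t\tabc"))
  m <- read_series_matrix(path)
  expect_identical(sum(is.na(m)), 5L)
})

test_that("format and validation errors are specific", {
  expect_error(read_series_matrix(write_series_lines("no table here")),
               "series_matrix_table_begin")
  expect_error(
    read_series_matrix(write_series_lines(
      c("!series_matrix_table_begin", "\"ID_REF\"\t\"S1\"", "\"P1\"\t1"))),
    "series_matrix_table_end")
  expect_error(
    read_series_matrix(write_series_lines(series_lines(
      "S1", c("\"P1\"\t1", "\"P1\"\t2")))),
    "duplicate probe.*P1")
  expect_error(
    read_series_matrix(write_series_lines(series_lines(
      c("S1", "S1"), "\"P1\"\t1\t2"))),
    "duplicate sample.*S1")
})

test_that("parsing ignores metadata-line order outside the block", {
  rows <- c("\"P1\"\t1.5\t2.5", "\"P2\"\t3.5\t4.5")
  a <- read_series_matrix(write_series_lines(series_lines(
    c("S1", "S2"), rows, extra_meta = c("!Meta_a\t1", "!Meta_b\t2"))))
  b <- read_series_matrix(write_series_lines(series_lines(
    c("S1", "S2"), rows, extra_meta = c("!Meta_b\t2", "!Meta_a\t1"))))
  expect_identical(a, b)
})

test_that("synthetic write -> parse round-trips values and missing mask", {
  sim <- generate_experiment(synthetic_config(n_genes = 300,
                                              missing_rate = 0.01, seed = 11))
  dir <- withr::local_tempdir()
  paths <- write_experiment(sim, dir)
  m <- read_series_matrix(paths[["series_matrix"]])
  expect_identical(dimnames(m), dimnames(sim$expression))
  expect_identical(is.na(m), is.na(sim$expression))
  keep <- !is.na(m)
  expect_identical(m[keep], sim$expression[keep])
})

test_that("gzip-compressed input reads identically", {
  sim <- generate_experiment(synthetic_config(n_genes = 150, seed = 4))
  dir <- withr::local_tempdir()
  paths <- write_experiment(sim, dir)
  gz <- file.path(dir, "series_matrix.txt.gz")
  con <- gzfile(gz, "wt")
  writeLines(readLines(paths[["series_matrix"]]), con)
  close(con)
  expect_identical(read_series_matrix(gz),
                   read_series_matrix(paths[["series_matrix"]]))
})

test_that("sample templates are validated", {
  tsv <- function(...) {
    path <- tempfile(fileext = ".tsv")
    writeLines(c("sample_id\trole", ...), path)
    path
  }
  tpl <- read_sample_template(tsv("S1\tcontrol", "S2\tControl",
                                  "S3\texperimental", "S4\tEXPERIMENTAL"),
                              experiment_id = "kd1")
  expect_identical(sum(tpl$role == "control"), 2L)
  expect_identical(sum(tpl$role == "experimental"), 2L)
  expect_identical(attr(tpl, "experiment_id"), "kd1")

  expect_error(read_sample_template(tsv("S1\tcontrol", "S2\tmock")), "mock")
  expect_error(read_sample_template(tsv("S1\tcontrol", "S2\tcontrol")),
               "no experimental samples")
  expect_error(read_sample_template(tsv("S1\texperimental")),
               "no control samples")
  expect_error(read_sample_template(tsv("S1\tcontrol", "S1\texperimental")),
               "S1")

  # comma-delimited variant
  csv <- tempfile(fileext = ".csv")
  writeLines(c("sample_id,role", "S1,control", "S2,experimental"), csv)
  expect_identical(nrow(read_sample_template(csv)), 2L)
})

test_that("platform annotation normalizes and splits symbols", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("ID\tGene Symbol", "P1\tabc1", "P2\tGeneA /// GeneB",
               "P3\t", "P4\t geneC "), path)
  pm <- read_platform_annotation(path)
  expect_identical(pm$symbol[pm$probe_id == "P1"], "ABC1")
  expect_setequal(pm$symbol[pm$probe_id == "P2"], c("GENEA", "GENEB"))
  expect_false("P3" %in% pm$probe_id)
  expect_identical(pm$symbol[pm$probe_id == "P4"], "GENEC")
  expect_error(read_platform_annotation(path, symbol_column = "nope"),
               "Gene Symbol")
})

test_that("every symbol from a generated platform table is clean", {
  set.seed(21)
  n <- 1000
  raw <- paste0(" gene", seq_len(n),
                ifelse(runif(n) < 0.3, " /// other", ""))
  path <- tempfile(fileext = ".tsv")
  writeLines(c("ID\tGene Symbol",
               paste0("P", seq_len(n), "\t", raw)), path)
  pm <- read_platform_annotation(path)
  expect_true(all(nzchar(pm$symbol)))
  expect_identical(pm$symbol, toupper(pm$symbol))
  expect_false(any(grepl("^\\s|\\s$", pm$symbol)))
})

test_that("probe collapse picks the minimum-p representative", {
  probe_results <- data.frame(
    id = c("p1", "p2", "p3", "p4", "p5"),
    mean_control = 1, mean_experimental = 2,
    t = c(2, -4, 1, NA, 0.5),
    p = c(0.02, 0.001, 0.5, NA, 0.9),
    call = c("up", "down", "neutral", "untestable", "neutral"),
    stringsAsFactors = FALSE)
  probe_map <- data.frame(
    probe_id = c("p1", "p2", "p3", "p4", "p5"),
    symbol = c("G1", "G1", "G2", "G2", "G3"),
    stringsAsFactors = FALSE)
  out <- collapse_to_genes(probe_results, probe_map)
  # G1: min p wins regardless of direction
  expect_identical(out$call[out$gene == "G1"], "down")
  expect_identical(out$p[out$gene == "G1"], 0.001)
  # G2: testable probe preferred over untestable
  expect_identical(out$call[out$gene == "G2"], "neutral")
  # G3: single probe passes through unchanged
  expect_identical(out$p[out$gene == "G3"], 0.9)
})

test_that("collapse ties break on the smallest probe id and unmapped drop", {
  probe_results <- data.frame(
    id = c("pB", "pA", "pX"), mean_control = 0, mean_experimental = 1,
    t = 1, p = c(0.05, 0.05, 0.01), call = "neutral",
    stringsAsFactors = FALSE)
  probe_map <- data.frame(probe_id = c("pA", "pB"), symbol = "G1",
                          stringsAsFactors = FALSE)
  expect_message(out <- collapse_to_genes(probe_results, probe_map),
                 "1 unmapped")
  expect_identical(out$probe, "pA")
})

test_that("collapsed gene p equals the minimum over its probes (random maps)", {
  set.seed(31)
  for (rep in 1:5) {
    n_probe <- 200
    probe_results <- data.frame(
      id = sprintf("p%03d", seq_len(n_probe)),
      mean_control = 0, mean_experimental = 1, t = 1,
      p = runif(n_probe),
      call = sample(c("up", "down", "neutral"), n_probe, replace = TRUE),
      stringsAsFactors = FALSE)
    probe_map <- data.frame(
      probe_id = probe_results$id,
      symbol = sprintf("G%02d", sample.int(40, n_probe, replace = TRUE)),
      stringsAsFactors = FALSE)
    out <- collapse_to_genes(probe_results, probe_map)
    # exhaustive per-gene scan
    for (g in out$gene) {
      probes <- probe_map$probe_id[probe_map$symbol == g]
      expect_identical(out$p[out$gene == g],
                       min(probe_results$p[probe_results$id %in% probes]))
    }
  }
})
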