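Package: l1screen
Title: Enrichment Screen for Host Genes of Intragenic LINE-1 Elements in
    Knockdown Expression Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Screens gene-knockdown expression experiments for coordinate
    regulation of genes that carry full-length intragenic LINE-1 (L1)
    retrotransposons. Parses GEO-style series-matrix expression tables,
    platform probe-to-symbol annotation and control/experimental sample
    templates; calls per-gene up/down regulation with pooled two-sample
    t-tests; builds strand-aware libraries of L1 host genes from interval
    annotations; tests each experiment for enrichment of L1 host genes
    among regulated genes with 2x2 odds ratios, Woolf confidence
    intervals and Pearson chi-squared tests; attaches label-shuffling
    permutation p-values and Storey bootstrap q-values; and classifies
    experiments by direction and magnitude of the association. A
    synthetic-data generator with planted ground truth supports testing
    every stage without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
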