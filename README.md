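# l1screen

Screening gene-knockdown expression experiments for coordinate regulation
of genes that host full-length intragenic LINE-1 (L1) retrotransposons.

## What it does, and for whom

Intragenic L1 elements — full-length copies (≥ 4,500 bp with a 5'UTR) lying
entirely inside gene bodies — can act as *cis*-regulatory elements of their
host genes. If knocking down a gene perturbs an L1-mediated regulatory
network, the genes that respond to that knockdown should be enriched for L1
host genes. `l1screen` implements that screen for researchers in
epigenomics and regulatory genomics working with deposited microarray
knockdown series: it reads GEO-style series-matrix expression tables,
platform probe annotation and control/experimental sample templates, and
reports per-experiment enrichment statistics and a final classification.

For one experiment, each gene is called `up`, `down` or `neutral` by a
pooled two-sample t-test at α = 0.01. For each direction *d* and each L1
host-gene library (all hosts, sense-strand hosts, antisense hosts), the
2×2 table

|            | regulated in *d* | not regulated |
|------------|------------------|---------------|
| L1 host    | a                | b             |
| not a host | c                | d             |

yields the odds ratio OR = ad/(bc) with the Woolf 95% CI
exp(ln OR ± 1.96 √(1/a + 1/b + 1/c + 1/d)), Pearson's chi-squared p-value
(1 df, no continuity correction), a permutation p-value from 100,000
uniform shuffles of the regulation labels (one-sided in the direction of
the observed deviation; the shuffle null is exactly hypergeometric), and a
Storey bootstrap q-value computed jointly over all rows of the run.
Experiments are then classified into seven groups by significant
direction(s) and OR side, and into four strand categories.

A synthetic-data generator (`generate_experiment()`) plants ground truth —
L1 membership, a target regulation odds ratio, effect sizes — and emits
the same file dialects the readers consume, so the whole pipeline is
testable without downloads.

## Worked example

```r
library(l1screen)

dir <- tempfile()
cfg <- synthetic_config(n_genes = 20000, target_or = 2.5,
                        p_reg_background = 0.02, seed = 42)
paths <- simulate_experiment(cfg, dir)

manifest <- data.frame(experiment_id = "demo_kd",
                       series_matrix = paths[["series_matrix"]],
                       platform = paths[["platform"]],
                       template = paths[["template"]])
config <- run_config(manifest,
                     library_all = paths[["library_all"]],
                     library_sense = paths[["library_sense"]],
                     library_antisense = paths[["library_antisense"]],
                     n_replicates = 10000, seed = 1,
                     out_dir = file.path(dir, "out"))
out <- run_screen(config)
out$results[, c("direction", "library", "a", "odds_ratio", "p_value",
                "perm_p", "q_value")]
#>   direction   library  a odds_ratio  p_value perm_p q_value
#> 1      down       all 33       2.04 0.000112 0.0002  0.0012
#> 2      down     sense 19       2.24 0.000589 0.0017  0.0051
#> 3      down antisense 14       1.69 0.055474 0.0467  0.0701
#> 4        up       all 27       1.50 0.046885 0.0366  0.0701
#> 5        up     sense 13       1.38 0.260717 0.1663  0.1663
#> 6        up antisense 14       1.57 0.100230 0.0787  0.0944
out$classification
#>   experiment_id    group strand_category
#> 1       demo_kd Down > 1      sense-only
```

The planted association (downregulation odds 2.5× higher for L1 hosts) is
recovered as a significant `Down > 1` call: 33 L1 host genes were called
down (OR 2.04, permutation p = 2×10⁻⁴, q = 0.0012), driven by the
sense-strand library. Note the call-level OR (2.04) sits below the planted
truth-level 2.5 — false-positive calls at α = 0.01 are independent of L1
status and attenuate the observed odds ratio toward 1; see the methods
vignette (`vignettes/l1-enrichment-screen.Rmd`) for the analysis.

Single statistics are available directly, e.g. the reference table of a
published XIAP knockdown:

```r
odds_ratio_ci(c(a = 28, b = 1312, c = 169, d = 18865))
#> $odds_ratio 2.38   $ci_low 1.59   $ci_high 3.57
chi_squared_test(c(a = 28, b = 1312, c = 169, d = 18865))$p_value
#> 1.39e-05
```

A command-line wrapper with `run`, `simulate`, `qvalue` and `classify`
subcommands ships in `inst/cli/l1screen.R`.

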