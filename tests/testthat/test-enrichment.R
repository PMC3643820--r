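xiap_table <- c(a = 28, b = 1312, c = 169, d = 18865)
ikbkap_table <- c(a = 22, b = 1315, c = 143, d = 18976)

test_that("contingency cells count the library/direction cross directly", {
  calls <- data.frame(gene = paste0("G", 1:10),
                      call = c("down", "down", "down", rep("neutral", 7)),
                      stringsAsFactors = FALSE)
  lib <- l1_library(paste0("G", c(1, 2, 5, 6)))
  expect_identical(build_contingency(calls, "down", lib),
                   c(a = 2L, b = 2L, c = 1L, d = 5L))
  # nothing regulated: a = c = 0, margins intact
  calls$call <- "neutral"
  expect_identical(build_contingency(calls, "down", lib),
                   c(a = 0L, b = 4L, c = 0L, d = 6L))
})

test_that("untestable genes leave the universe; degenerate margins error", {
  calls <- data.frame(gene = paste0("G", 1:6),
                      call = c("down", "untestable", "untestable",
                               "neutral", "neutral", "up"),
                      stringsAsFactors = FALSE)
  lib <- l1_library(c("G1", "G4"))
  tb <- build_contingency(calls, "down", lib)
  expect_identical(sum(tb), 4L)   # universe excludes the 2 untestable genes
  expect_error(build_contingency(calls, "down", l1_library(c("G2", "G3"))),
               "degenerate")
  expect_error(build_contingency(calls, "down",
                                 l1_library(paste0("G", 1:6))),
               "degenerate")
})

test_that("contingency cells equal a brute-force per-gene recount", {
  set.seed(23)
  for (rep in 1:5) {
    n <- 300
    calls <- data.frame(
      gene = sprintf("G%03d", seq_len(n)),
      call = sample(c("down", "up", "neutral", "untestable"), n,
                    replace = TRUE, prob = c(0.1, 0.1, 0.7, 0.1)),
      stringsAsFactors = FALSE)
    lib <- l1_library(sample(calls$gene, 60))
    for (direction in c("down", "up")) {
      tb <- build_contingency(calls, direction, lib)
      a <- b <- c <- d <- 0L
      for (i in seq_len(n)) {
        cl <- calls$call[i]
        if (cl == "untestable") next
        inl <- calls$gene[i] %in% lib$genes
        hit <- cl == direction
        if (inl && hit) a <- a + 1L else if (inl) b <- b + 1L
        else if (hit) c <- c + 1L else d <- d + 1L
      }
      expect_identical(tb, c(a = a, b = b, c = c, d = d))
    }
  }
})

test_that("chi-squared reproduces both printed example tables exactly", {
  t2 <- chi_squared_test(xiap_table)
  expect_equal(signif(t2$p_value, 3), 1.39e-5)
  t3 <- chi_squared_test(ikbkap_table)
  expect_equal(signif(t3$p_value, 3), 3.90e-4)
  # independence gives chi2 = 0, p = 1
  flat <- chi_squared_test(c(a = 10, b = 10, c = 10, d = 10))
  expect_equal(flat$chi2, 0)
  expect_equal(flat$p_value, 1)
})

test_that("chi-squared equals the sum((O-E)^2/E) expansion on random tables", {
  set.seed(29)
  for (rep in 1:20) {
    tb <- c(a = rpois(1, 20) + 1L, b = rpois(1, 500) + 1L,
            c = rpois(1, 50) + 1L, d = rpois(1, 5000) + 1L)
    res <- chi_squared_test(tb)
    expect_equal(res$chi2, brute_chi2(tb["a"], tb["b"], tb["c"], tb["d"]),
                 tolerance = 1e-10)
    expect_equal(res$p_value, pchisq(res$chi2, 1, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("odds ratios reproduce the printed examples and Woolf CI brackets", {
  t2 <- odds_ratio_ci(xiap_table)
  expect_equal(round(t2$odds_ratio, 2), 2.38)
  t3 <- odds_ratio_ci(ikbkap_table)
  expect_equal(round(t3$odds_ratio, 2), 2.22)
  expect_true(t2$ci_low <= t2$odds_ratio && t2$odds_ratio <= t2$ci_high)
  # symmetric table: OR 1, CI straddles 1
  sym <- odds_ratio_ci(c(a = 5, b = 5, c = 5, d = 5))
  expect_equal(sym$odds_ratio, 1)
  expect_true(sym$ci_low < 1 && sym$ci_high > 1)
})

test_that("OR is invariant to swapping cells b and c", {
  set.seed(37)
  for (rep in 1:10) {
    tb <- c(a = rpois(1, 15) + 1L, b = rpois(1, 800) + 1L,
            c = rpois(1, 90) + 1L, d = rpois(1, 9000) + 1L)
    swapped <- tb[c("a", "c", "b", "d")]
    names(swapped) <- c("a", "b", "c", "d")
    expect_equal(odds_ratio_ci(tb)$odds_ratio,
                 odds_ratio_ci(swapped)$odds_ratio, tolerance = 1e-12)
    expect_equal(chi_squared_test(tb)$chi2, chi_squared_test(swapped)$chi2,
                 tolerance = 1e-10)
  }
})

test_that("zero cells get the Haldane-Anscombe 0.5 for OR only", {
  tb <- c(a = 0, b = 40, c = 10, d = 450)
  or <- odds_ratio_ci(tb)
  manual <- (0.5 * 450.5) / (40.5 * 10.5)
  expect_equal(or$odds_ratio, manual, tolerance = 1e-12)
  expect_true(is.finite(or$ci_low) && or$ci_low > 0)
  # chi-squared still uses the raw counts
  expect_equal(chi_squared_test(tb)$chi2, brute_chi2(0, 40, 10, 450),
               tolerance = 1e-10)
})

test_that("analyze_experiment emits exactly six populated rows", {
  sim <- generate_experiment(synthetic_config(n_genes = 800, seed = 41,
                                              target_or = 3,
                                              p_reg_background = 0.05))
  calls <- data.frame(gene = sim$truth$gene,
                      call = ifelse(sim$truth$true_direction == "none",
                                    "neutral", sim$truth$true_direction),
                      stringsAsFactors = FALSE)
  res <- analyze_experiment(calls, sim$libraries, "exp1")
  expect_identical(nrow(res), 6L)
  expect_setequal(res$direction, c("down", "up"))
  expect_setequal(res$library, c("all", "sense", "antisense"))
  expect_true(all(!res$degenerate))
  expect_true(all(res$a + res$b == length(sim$libraries$all$genes)
                  | res$library != "all"))
  expect_true(all(is.na(res$perm_p)) && all(is.na(res$q_value)))
})

test_that("degenerate directions are flagged, not dropped", {
  calls <- data.frame(gene = paste0("G", 1:50),
                      call = c(rep("neutral", 49), "down"),
                      stringsAsFactors = FALSE)
  libs <- list(all = l1_library(paste0("G", 1:10)),
               sense = l1_library(paste0("G", 1:5)),
               antisense = l1_library(paste0("G", 6:10)))
  res <- analyze_experiment(calls, libs, "exp1")
  expect_identical(nrow(res), 6L)
  up <- res[res$direction == "up", ]
  expect_true(all(up$degenerate))   # nobody is upregulated
  expect_true(all(is.na(up$p_value)))
  expect_identical(up$a, rep(0L, 3))  # counts still reported
})

test_that("Woolf CI covers a planted truth-level odds ratio", {
  # regulation calls taken from the planted truth isolate the estimator
  # from t-test misclassification; coverage should be near nominal
  set.seed(43)
  n_sims <- 100
  covered <- 0L
  for (s in seq_len(n_sims)) {
    cfg <- synthetic_config(n_genes = 20000, target_or = 2.5,
                            p_reg_background = 0.02, seed = 5000 + s)
    sim <- generate_experiment(cfg)
    calls <- data.frame(gene = sim$truth$gene,
                        call = ifelse(sim$truth$true_direction == "none",
                                      "neutral", sim$truth$true_direction),
                        stringsAsFactors = FALSE)
    down <- sim$truth$true_direction == "down"
    tb <- build_contingency(calls, "down", sim$libraries$all)
    or <- odds_ratio_ci(tb)
    if (or$ci_low <= 2.5 && 2.5 <= or$ci_high) covered <- covered + 1L
  }
  expect_gte(covered, 90L)
})

test_that("null experiments give calibrated enrichment p-values", {
  # truth-level labels under target_or = 1: chi-squared p should be uniform
  set.seed(47)
  pvals <- c()
  for (s in 1:60) {
    cfg <- synthetic_config(n_genes = 10000, target_or = 1,
                            p_reg_background = 0.1, seed = 7000 + s)
    sim <- generate_experiment(cfg)
    calls <- data.frame(gene = sim$truth$gene,
                        call = ifelse(sim$truth$true_direction == "none",
                                      "neutral", sim$truth$true_direction),
                        stringsAsFactors = FALSE)
    for (d in c("down", "up")) {
      tb <- build_contingency(calls, d, sim$libraries$all)
      pvals <- c(pvals, chi_squared_test(tb)$p_value)
    }
  }
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.05)
})
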