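# Variant positional-clustering and genotype-phenotype association statistics.

test_that("binomial window test matches the closed form and is monotone", {
  expect_equal(binomial_window_test(0, 10, 5, 100), 1)
  # hand expansion: P(X >= 2 | n = 5, q = 0.1)
  want <- 1 - 0.9^5 - 5 * 0.1 * 0.9^4
  expect_equal(binomial_window_test(2, 5, 10, 100), want)
  expect_equal(binomial_window_test(2, 5, 10, 100),
               oracle_binom_upper(2, 5, 0.1))
  # monotone: more variants in the window never increases p
  ps_k <- vapply(0:10, binomial_window_test, numeric(1),
                 n = 20, w = 10, L = 100)
  expect_true(all(diff(ps_k) <= 0))
  # wider windows never decrease p at fixed k
  ps_w <- vapply(c(5, 10, 20, 40), binomial_window_test, numeric(1),
                 k = 4, n = 20, L = 100)
  expect_true(all(diff(ps_w) >= 0))
  expect_error(binomial_window_test(5, 4, 10, 100), "k <= n")
  expect_error(binomial_window_test(1, 4, 200, 100), "w <= L")
})

test_that("the sliding-window scan finds a planted cluster", {
  pos <- c(rep(50:60, 2), sample(1:400, 10))
  scan <- binomial_window_scan(pos, w = 20, L = 400, step = 5)
  best <- scan[which.min(scan$p), ]
  expect_true(best$start <= 50 && best$end >= 60)
  expect_true(all(scan$p_bonferroni >= scan$p))
})

test_that("Fisher's exact test matches enumeration and the R reference", {
  r <- fisher_exact_2x2(c(5, 5, 5, 5))
  expect_equal(r$p_two_sided, 1)
  expect_equal(r$odds_ratio, 1)
  r2 <- fisher_exact_2x2(c(2, 1, 1, 2))
  expect_equal(r2$p_two_sided, 1)  # full enumeration over x in 0..3
  # the exon-4 style table: one-sided tail is a single term
  r3 <- fisher_exact_2x2(c(9, 2, 0, 32))
  expect_equal(r3$p_one_sided, choose(11, 9) * choose(32, 0) / choose(43, 9))
  o3 <- oracle_fisher(9, 2, 0, 32)
  expect_equal(r3$p_one_sided, o3$p_one_sided)
  expect_equal(r3$p_two_sided, o3$p_two_sided)
  # random tables agree with enumeration and with stats::fisher.test
  set.seed(61)
  for (i in 1:50) {
    cells <- as.vector(stats::rmultinom(1, sample(10:50, 1), rep(0.25, 4)))
    ours <- fisher_exact_2x2(cells)
    orc <- oracle_fisher(cells[1], cells[2], cells[3], cells[4])
    expect_equal(ours$p_one_sided, orc$p_one_sided)
    expect_equal(ours$p_two_sided, orc$p_two_sided)
    m <- matrix(cells, 2, byrow = TRUE)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) {
      ref <- stats::fisher.test(m)
      expect_equal(ours$p_two_sided, ref$p.value, tolerance = 1e-10)
      ref1 <- stats::fisher.test(m, alternative = "greater")
      expect_equal(ours$p_one_sided, ref1$p.value, tolerance = 1e-10)
    }
  }
  expect_error(fisher_exact_2x2(c(0, 0, 0, 0)), "empty")
  # continuity-corrected odds ratio with a zero cell
  expect_equal(fisher_exact_2x2(c(9, 2, 0, 32))$odds_ratio,
               (9.5 * 32.5) / (2.5 * 0.5))
})

test_that("cohort summaries are exact count ratios, reproducing the pooled margins", {
  sim <- generate_cohort(simulation_profile("cohort_paper"), seed = 3)
  s <- cohort_summary(sim$cohort)
  ec <- s[s$flag == "extracardiac", ]
  expect_equal(ec$n[ec$stratum == "overall"], 29)
  expect_equal(ec$total[ec$stratum == "overall"], 70)
  expect_equal(ec$percent[ec$stratum == "overall"], 41.4)
  expect_equal(ec$n[ec$stratum == "LoF"], 18)
  expect_equal(ec$n[ec$stratum == "missense"], 11)
  nr <- s[s$flag == "neuro" & s$stratum == "overall", ]
  expect_equal(nr$n, 13)
  expect_equal(nr$percent, 18.6)
  # percentages always re-derive from counts
  expect_equal(s$percent, round(100 * s$n / s$total, 1))
  # all-false cohort
  flat <- as_cohort_table(data.frame(
    patient_id = c("a", "b"), variant_class = c("LoF", "missense"),
    residue_position = c(10L, 20L), extracardiac = FALSE,
    pa_cdh = FALSE, neuro = FALSE))
  s0 <- cohort_summary(flat)
  expect_true(all(s0$percent == 0))
})

test_that("phenotype association builds the printed 2x2 tables from patient rows", {
  sim <- generate_cohort(simulation_profile("cohort_paper"), seed = 3)
  pa <- phenotype_association(sim$cohort, "pa_cdh", "exon4_missense")
  expect_equal(unname(pa$table), matrix(c(9, 2, 0, 32), 2, byrow = TRUE))
  ec <- phenotype_association(sim$cohort, "extracardiac", "variant_class")
  expect_equal(unname(ec$table), matrix(c(18, 9, 11, 32), 2, byrow = TRUE))
  # random cohort vs hand tabulation
  set.seed(67)
  co <- as_cohort_table(data.frame(
    patient_id = sprintf("p%02d", 1:40),
    variant_class = sample(c("LoF", "missense"), 40, replace = TRUE),
    residue_position = sample(c(NA, 1:595), 40, replace = TRUE),
    extracardiac = sample(c(TRUE, FALSE), 40, replace = TRUE),
    pa_cdh = sample(c(TRUE, FALSE), 40, replace = TRUE),
    neuro = FALSE))
  got <- phenotype_association(co, "extracardiac", "variant_class")
  lof <- co$variant_class == "LoF"
  expect_equal(unname(got$table),
               matrix(c(sum(co$extracardiac & lof), sum(!co$extracardiac & lof),
                        sum(co$extracardiac & !lof),
                        sum(!co$extracardiac & !lof)), 2, byrow = TRUE))
  # flag constant across strata on balanced strata: no association
  bal <- as_cohort_table(data.frame(
    patient_id = sprintf("q%02d", 1:20),
    variant_class = rep(c("LoF", "missense"), each = 10),
    residue_position = 100L,
    extracardiac = rep(c(TRUE, FALSE), 10), pa_cdh = FALSE, neuro = FALSE))
  res <- phenotype_association(bal, "extracardiac", "variant_class")
  expect_equal(res$fisher$p_two_sided, 1)
  expect_equal(res$fisher$odds_ratio, 1)
})

test_that("cohort tables validate their invariants on read", {
  f <- withr::local_tempfile()
  writeLines(c("patient_id\tvariant_class\tresidue_position\textracardiac\tpa_cdh\tneuro",
               "p1\tLoF\t100\tTRUE\tFALSE\tFALSE",
               "p2\tmissense\t450\tFALSE\tFALSE\tTRUE"), f)
  co <- read_cohort(f)
  expect_s3_class(co, "CohortTable")
  expect_equal(nrow(co), 2)
  writeLines(c("patient_id\tvariant_class\tresidue_position\textracardiac\tpa_cdh\tneuro",
               "p1\tnonsense_class\t100\tTRUE\tFALSE\tFALSE"), f)
  expect_error(read_cohort(f), "variant_class")
})
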