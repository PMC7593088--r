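# Synthetic-data generators: determinism, exact planting, plant-and-recover.

small_profile <- function(name = "wt_day4", ...) {
  simulation_profile(name, modifyList(small_epigenome_overrides(), list(...)))
}

test_that("generators are pure functions of (profile, seed)", {
  prof <- small_profile()
  a1 <- generate_genome(prof, seed = 5)
  a2 <- generate_genome(prof, seed = 5)
  expect_identical(a1, a2)
  a3 <- generate_genome(prof, seed = 6)
  expect_false(identical(a1$genes$start, a3$genes$start))

  p1 <- generate_peaksets(prof, a1, seed = 5)
  p2 <- generate_peaksets(prof, a1, seed = 5)
  expect_identical(p1$truth, p2$truth)
  expect_identical(p1$chip_ref$peaks, p2$chip_ref$peaks)

  s1 <- generate_peak_sequences(prof, p1$chip_ref$peaks,
                                p1$truth$state[match(p1$chip_ref$peaks$id,
                                                     p1$truth$peak_id)],
                                seed = 5)
  s2 <- generate_peak_sequences(prof, p1$chip_ref$peaks,
                                p1$truth$state[match(p1$chip_ref$peaks$id,
                                                     p1$truth$peak_id)],
                                seed = 5)
  expect_identical(s1$sequences$codes, s2$sequences$codes)
})

test_that("genome generation respects its construction invariants", {
  prof <- small_profile()
  ann <- generate_genome(prof, seed = 9)
  g <- ann$genes
  expect_equal(nrow(g), 400)
  expect_true(all(g$start >= 0 & g$end <= ann$chrom_sizes[g$chrom]))
  # TSS spacing within each chromosome
  for (ch in unique(g$chrom)) {
    tss <- sort(g$tss[g$chrom == ch])
    if (length(tss) > 1) {
      expect_true(all(diff(tss) >= prof$genome$min_tss_spacing))
    }
  }
  # exons inside gene bodies
  e <- ann$exons
  gi <- match(e$gene_id, g$gene_id)
  expect_true(all(e$start >= g$start[gi] & e$end <= g$end[gi]))
  # infeasible spacing errors out
  bad <- small_profile()
  bad$genome$n_genes <- 1e6
  expect_error(generate_genome(bad, seed = 1), "cannot fit")
})

test_that("peak generation plants membership fractions exactly", {
  prof <- small_profile()
  ann <- generate_genome(prof, seed = 9)
  ps <- generate_peaksets(prof, ann, seed = 9)
  n_open_want <- round(prof$peaks$frac_open * prof$peaks$n_chip)
  expect_equal(sum(ps$truth$state == "OPEN"), n_open_want)
  # the classifier recovers the planted states exactly (overlap construction)
  cls <- classify_open_closed(ps$chip_ref, ps$atac)
  merged <- merge(cls$per_peak, ps$truth, by = "peak_id")
  expect_equal(merged$state.x, merged$state.y)
  # frac_open = 0 plants and recovers zero open peaks
  prof0 <- small_profile()
  prof0$peaks$frac_open <- 0
  ps0 <- generate_peaksets(prof0, ann, seed = 9)
  cls0 <- classify_open_closed(ps0$chip_ref, ps0$atac)
  expect_equal(cls0$n_open, 0)
})

test_that("genotype profiles plant reduced/increased sets at the configured size", {
  prof <- small_profile("r456g_day4", genotype = list(n_other = 1500))
  ann <- generate_genome(prof, seed = 9)
  ps <- generate_peaksets(prof, ann, seed = 9)
  tr <- ps$truth
  expect_equal(sum(tr$call == "REDUCED"),
               round(prof$genotype$frac_reduced * prof$peaks$n_chip))
  expect_equal(sum(tr$call == "INCREASED"),
               round(prof$genotype$frac_increased * prof$genotype$n_other))
  expect_equal(sum(tr$in_other), prof$genotype$n_other)
  expect_equal(sum(tr$in_reference), prof$peaks$n_chip)
  expect_equal(nrow(ps$chip_other$peaks), prof$genotype$n_other)
  # reduced peaks carry the planted open fraction
  red <- tr[tr$call == "REDUCED", ]
  expect_equal(sum(red$state == "OPEN"),
               round(prof$genotype$frac_open_reduced * nrow(red)))
})

test_that("planted motif instances are recovered by scanning", {
  prof <- small_profile()
  # planting rate 1: every open sequence has a scan hit at threshold 0.8
  prof$motifs$open_rate <- 1
  prof$motifs$closed_rate <- 0
  cs <- simulate_class_sequences(prof, seed = 21, n_open = 120,
                                 n_closed = 120)
  lib <- default_motif_library()
  hits_open <- scan_hit_counts(
    seqset_subset(cs$sequences, cs$states == "OPEN"), lib$GATA) > 0
  expect_true(all(hits_open))
  # planting rate 0: the closed-class GATA hit rate matches shuffled background
  fg_closed <- seqset_subset(cs$sequences, cs$states == "CLOSED")
  bg <- sample_background(fg_closed, n_bg_per_fg = 10, seed = 21)
  fg_rate <- mean(scan_hit_counts(fg_closed, lib$GATA) > 0)
  bg_rate <- mean(scan_hit_counts(bg, lib$GATA) > 0)
  se <- sqrt(bg_rate * (1 - bg_rate) / 120)
  expect_lt(abs(fg_rate - bg_rate), 4 * se + 1e-9)
})

test_that("expression generation plants the DE/association structure exactly", {
  prof <- simulation_profile(
    "wt_expression",
    list(genome = list(n_genes = 800),
         peaks = list(n_chip = 800, n_atac = 1600),
         expression = list(n_de = 120)))
  ann <- generate_genome(prof, seed = 31)
  plan <- plan_integration(prof, ann, seed = 31)
  expect_length(plan$de_genes, 120)
  expect_length(plan$assoc_genes, round(0.364 * 120))
  expect_length(plan$assoc_up_genes, round(0.56 * length(plan$assoc_genes)))
  expect_length(plan$bg_assoc_genes, round(0.25 * (800 - 120)))
  expect_true(all(plan$assoc_genes %in% plan$de_genes))
  ex <- generate_expression(prof, ann, seed = 31, plan = plan)
  expect_equal(sum(ex$truth$is_de), 120)
  expect_identical(sort(ex$truth$gene_id[ex$truth$assoc]),
                   sort(plan$assoc_genes))
  # every association-plan gene receives exactly one closed proximal peak
  ps <- generate_peaksets(prof, ann, seed = 32,
                          assoc_plan = plan$assoc_plan)
  planted <- table(ps$truth$assoc_gene)
  expect_setequal(names(planted), plan$assoc_plan$gene_id)
  expect_true(all(planted == 1))
  expect_true(all(ps$truth$state[!is.na(ps$truth$assoc_gene)] == "CLOSED"))
  # and the assignment step recovers it within the window
  assoc <- associate_peaks_to_genes(
    ps$chip_ref$peaks[ps$chip_ref$peaks$id %in%
                        ps$truth$peak_id[ps$truth$state == "CLOSED"], ],
    ann, max_distance = 5e4)
  expect_true(all(plan$assoc_plan$gene_id %in% names(assoc$gene_map)))
})

test_that("a null expression table yields an alpha-consistent discovery count", {
  prof <- simulation_profile(
    "wt_expression",
    list(genome = list(n_genes = 500),
         peaks = list(n_chip = 500, n_atac = 1000),
         expression = list(n_de = 0)))
  ann <- generate_genome(prof, seed = 41)
  ex <- generate_expression(prof, ann, seed = 41)
  de <- differential_expression(ex$expr)
  # BH at 5% on a global null: expected false discoveries near zero
  expect_lte(sum(de$call != "NS"), 5)
})

test_that("cohort generation honours exact margins and seeds", {
  prof <- simulation_profile("cohort_paper")
  g1 <- generate_cohort(prof, seed = 2)
  g2 <- generate_cohort(prof, seed = 2)
  expect_identical(g1$cohort, g2$cohort)
  co <- g1$cohort
  expect_equal(nrow(co), 70)
  expect_equal(sum(co$variant_class == "LoF"), 27)
  expect_equal(sum(co$variant_class == "missense"), 43)
  e4 <- co$variant_class == "missense" & !is.na(co$residue_position) &
    co$residue_position >= 435 & co$residue_position <= 477
  expect_equal(sum(e4), 11)
  expect_equal(sum(co$pa_cdh & e4), 9)
  expect_equal(sum(co$pa_cdh & co$variant_class == "missense" & !e4), 0)
  expect_equal(sum(co$extracardiac), 29)
  # rates mode with zero rates
  prof0 <- simulation_profile("cohort_paper")
  prof0$cohort$mode <- "rates"
  prof0$cohort$rates <- list(
    extracardiac = list(LoF = 0, missense = 0),
    pa_cdh = list(LoF = 0, missense = 0),
    neuro = list(LoF = 0, missense = 0))
  co0 <- generate_cohort(prof0, seed = 2)$cohort
  expect_false(any(co0$extracardiac | co0$pa_cdh | co0$neuro))
})
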