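# Open/closed chromatin classification and genotype peak-set comparison.

make_ps <- function(df, assay = "CHIP", name = "x") {
  peak_set(df, name = name, assay = assay)
}

test_that("classification degenerate cases behave as documented", {
  chip <- make_ps(data.frame(id = c("c1", "c2"), chrom = "chr1",
                             start = c(100, 500), end = c(200, 600)))
  empty_atac <- make_ps(data.frame(id = character(), chrom = character(),
                                   start = numeric(), end = numeric()),
                        assay = "ATAC")
  cls <- classify_open_closed(chip, empty_atac)
  expect_equal(cls$frac_open, 0)
  expect_true(all(cls$per_peak$state == "CLOSED"))

  cover <- make_ps(data.frame(id = c("a1", "a2"), chrom = "chr1",
                              start = c(50, 450), end = c(250, 650)),
                   assay = "ATAC")
  cls2 <- classify_open_closed(chip, cover)
  expect_equal(cls2$frac_open, 1)
  expect_equal(cls2$per_peak$overlap_bp, c(100, 100))
  expect_error(classify_open_closed(empty_atac, cover), "empty ChIP")
})

test_that("classification is idempotent under duplicated accessibility evidence", {
  set.seed(3)
  chip <- make_ps(random_intervals(80, prefix = "c"))
  atac_df <- random_intervals(60, prefix = "a")
  atac <- make_ps(atac_df, assay = "ATAC")
  dup_df <- atac_df
  dup_df$id <- paste0(dup_df$id, "_dup")
  atac2 <- make_ps(rbind(atac_df, dup_df), assay = "ATAC")
  c1 <- classify_open_closed(chip, atac)
  c2 <- classify_open_closed(chip, atac2)
  expect_equal(c1$per_peak$state, c2$per_peak$state)
  expect_equal(c1$frac_open, c2$frac_open)
})

test_that("frac_open is monotone non-decreasing as min_overlap decreases", {
  set.seed(5)
  chip <- make_ps(random_intervals(120, prefix = "c"))
  atac <- make_ps(random_intervals(120, prefix = "a"), assay = "ATAC")
  fracs <- vapply(c(1, 10, 50, 100), function(mo) {
    classify_open_closed(chip, atac, min_overlap = mo)$frac_open
  }, numeric(1))
  expect_true(all(diff(fracs) <= 0))
})

test_that("location distribution equals a per-peak recount", {
  set.seed(19)
  ann <- random_annotation(20)
  chip <- make_ps(random_intervals(100, max_pos = 49000, prefix = "c"))
  atac <- make_ps(random_intervals(50, max_pos = 49000, prefix = "a"),
                  assay = "ATAC")
  cls <- classify_open_closed(chip, atac)
  tab <- location_distribution(cls, chip, ann)
  feat <- oracle_feature(chip$peaks, ann)
  state <- cls$per_peak$state[match(chip$peaks$id, cls$per_peak$peak_id)]
  for (i in seq_len(nrow(tab))) {
    expect_equal(tab$n[i],
                 sum(feat == tab$feature[i] & state == tab$state[i]))
  }
  # per-state fractions sum to 1 (when the state is populated)
  for (st in c("OPEN", "CLOSED")) {
    n_st <- sum(tab$n[tab$state == st])
    if (n_st > 0) expect_equal(sum(tab$fraction[tab$state == st]), 1)
  }
  expect_equal(sum(tab$n), nrow(chip$peaks))
  # mismatched classification is rejected
  other <- make_ps(random_intervals(10, prefix = "z"))
  expect_error(location_distribution(cls, other, ann), "different peak ids")
})

test_that("genotype comparison uses the figure denominators and validates ids", {
  ref <- make_ps(data.frame(id = c("p1", "p2", "p3"), chrom = "chr1",
                            start = c(0, 100, 200), end = c(50, 150, 250)))
  oth <- make_ps(data.frame(id = c("p2", "p3", "q1"), chrom = "chr1",
                            start = c(100, 200, 300), end = c(150, 250, 350)))
  calls <- data.frame(peak_id = c("p1", "p2", "p3", "q1"),
                      call = c("REDUCED", "UNCHANGED", "UNCHANGED",
                               "INCREASED"))
  cmp <- compare_genotype_peaksets(ref, oth, calls)
  expect_equal(cmp$lost, "p1")
  expect_equal(cmp$gained, "q1")
  expect_equal(cmp$lost_frac, 1 / 3)
  expect_equal(cmp$gained_frac, 1 / 3)
  expect_setequal(cmp$shared, c("p2", "p3"))
  # identical profiles -> no calls -> empty LOST/GAINED
  none <- data.frame(peak_id = c("p1", "p2", "p3", "q1"), call = "UNCHANGED")
  cmp0 <- compare_genotype_peaksets(ref, oth, none)
  expect_equal(cmp0$n_lost + cmp0$n_gained, 0)
  # all reference peaks reduced -> LOST fraction 1
  allred <- data.frame(peak_id = c("p1", "p2", "p3"), call = "REDUCED")
  expect_equal(compare_genotype_peaksets(ref, oth, allred)$lost_frac, 1)
  bad <- data.frame(peak_id = "nope", call = "REDUCED")
  expect_error(compare_genotype_peaksets(ref, oth, bad), "unknown peak ids")
})

test_that("accessibility of differential peaks splits LOST/GAINED by overlap", {
  ref <- make_ps(data.frame(id = c("p1", "p2"), chrom = "chr1",
                            start = c(0, 1000), end = c(100, 1100)))
  oth <- make_ps(data.frame(id = "q1", chrom = "chr1",
                            start = 2000, end = 2100))
  calls <- data.frame(peak_id = c("p1", "p2", "q1"),
                      call = c("REDUCED", "REDUCED", "INCREASED"))
  cmp <- compare_genotype_peaksets(ref, oth, calls)
  union_df <- rbind(ref$peaks[, c("id", "chrom", "start", "end")],
                    oth$peaks[, c("id", "chrom", "start", "end")])
  atac_all <- make_ps(data.frame(id = c("a1", "a2"), chrom = "chr1",
                                 start = c(0, 950), end = c(150, 1200)),
                      assay = "ATAC")
  acc <- accessibility_of_differential_peaks(cmp, union_df, atac_all)
  expect_equal(acc$frac_open_lost, 1)
  expect_equal(acc$frac_open_gained, 0)
  expect_setequal(acc$lost_open, c("p1", "p2"))
  expect_equal(acc$gained_closed, "q1")
  # empty accessibility set -> all closed
  atac_none <- make_ps(data.frame(id = character(), chrom = character(),
                                  start = numeric(), end = numeric()),
                       assay = "ATAC")
  acc0 <- accessibility_of_differential_peaks(cmp, union_df, atac_none)
  expect_equal(acc0$frac_open_lost, 0)
  # nothing differential -> error
  cmp0 <- compare_genotype_peaksets(
    ref, oth, data.frame(peak_id = "p1", call = "UNCHANGED"))
  expect_error(accessibility_of_differential_peaks(cmp0, union_df, atac_all),
               "no LOST and no GAINED")
})
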