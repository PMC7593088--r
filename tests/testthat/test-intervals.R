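# Interval domain types, format readers/writers and interval arithmetic.

test_that("BED6 and narrowPeak records map to peaks with preserved coordinates", {
  f <- withr::local_tempfile()
  writeLines("chr1\t100\t200\tpk1\t0\t+", f)
  ps <- read_peaks(f, "BED6")
  expect_equal(ps$peaks$id, "pk1")
  expect_equal(ps$peaks$start, 100)
  expect_equal(ps$peaks$end, 200)
  expect_equal(ps$peaks$strand, "+")

  f2 <- withr::local_tempfile()
  writeLines("chr1\t100\t200\tpk1\t0\t.\t5.5\t-1\t-1\t50", f2)
  np <- read_peaks(f2, "narrowPeak")
  expect_equal(np$peaks$summit_offset, 50L)

  # auto ids for "."
  f3 <- withr::local_tempfile()
  writeLines(c("chr1\t10\t20\t.\t0\t.", "chr1\t30\t40\t.\t0\t."), f3)
  expect_equal(read_peaks(f3, "BED6")$peaks$id, c("peak_1", "peak_2"))
})

test_that("malformed peak files fail with the offending line number", {
  f <- withr::local_tempfile()
  writeLines(c("chr1\t10\t20\tp1\t0\t+", "chr1\t10"), f)
  expect_error(read_peaks(f, "BED6"), "line 2")
  writeLines(c("chr1\t20\t10\tp1\t0\t+"), f)
  expect_error(read_peaks(f, "BED6"), "line 1")
  writeLines(c("chr1\t10\t20\tp1\t0\t+", "chr2\t10\t20\tp1\t0\t+"), f)
  expect_error(read_peaks(f, "BED6"), "duplicate")
})

test_that("peak writers round-trip random records byte-for-byte fields", {
  set.seed(42)
  for (fmt in c("BED6", "narrowPeak")) {
    df <- random_intervals(100, prefix = "rp")
    df$summit_offset <- sample(0:50, 100, replace = TRUE)
    ps <- peak_set(df, name = "rt")
    f <- withr::local_tempfile()
    write_peaks(ps, f, fmt)
    back <- read_peaks(f, fmt)
    expect_equal(back$peaks$id, ps$peaks$id)
    expect_equal(back$peaks$start, ps$peaks$start)
    expect_equal(back$peaks$end, ps$peaks$end)
    if (fmt == "narrowPeak") {
      expect_equal(back$peaks$summit_offset, ps$peaks$summit_offset)
    }
    # writing again gives identical bytes (deterministic output)
    f2 <- withr::local_tempfile()
    write_peaks(back, f2, fmt)
    expect_identical(readLines(f), readLines(f2))
  }
  # empty set -> empty file
  f <- withr::local_tempfile()
  write_peaks(peak_set(data.frame(id = character(), chrom = character(),
                                  start = numeric(), end = numeric())), f)
  expect_length(readLines(f), 0)
})

test_that("GTF coordinates convert between 1-based inclusive and half-open", {
  f <- withr::local_tempfile()
  writeLines(c(
    'chr1\tsrc\tgene\t1001\t2000\t.\t+\t.\tgene_id "gp";',
    'chr1\tsrc\tgene\t5001\t6000\t.\t-\t.\tgene_id "gm";',
    'chr1\tsrc\texon\t1001\t1200\t.\t+\t.\tgene_id "gp";'), f)
  ann <- read_gene_annotation(f, "GTF")
  gp <- ann$genes[ann$genes$gene_id == "gp", ]
  expect_equal(gp$start, 1000)
  expect_equal(gp$end, 2000)
  expect_equal(gp$tss, 1000)
  gm <- ann$genes[ann$genes$gene_id == "gm", ]
  expect_equal(gm$tss, 5999)
  expect_equal(ann$exons$start, 1000)
  # exon without parent gene
  writeLines('chr1\tsrc\texon\t100\t200\t.\t+\t.\tgene_id "orphan";', f)
  expect_error(read_gene_annotation(f, "GTF"), "without parent gene")
})

test_that("a 50-gene annotation round-trips through GTF preserving all TSS", {
  set.seed(7)
  ann <- random_annotation(50)
  f <- withr::local_tempfile()
  write_gene_annotation(ann, f)
  back <- read_gene_annotation(f, "GTF",
                               chrom_sizes = ann$chrom_sizes)
  expect_equal(back$genes[order(back$genes$gene_id), "tss"],
               ann$genes[order(ann$genes$gene_id), "tss"])
  expect_equal(nrow(back$genes), 50)
  # independent reader agrees on the coordinate convention
  gr <- rtracklayer::import(f, format = "gtf")
  gr <- gr[gr$type == "gene"]
  ours <- ann$genes[match(gr$gene_id, ann$genes$gene_id), ]
  expect_equal(BiocGenerics::start(gr) - 1L, ours$start)
  expect_equal(BiocGenerics::end(gr), ours$end)
})

test_that("overlap_query matches the all-pairs oracle and its invariants", {
  # half-open adjacency does not overlap
  a <- data.frame(id = "a1", chrom = "chr1", start = 0, end = 10)
  b <- data.frame(id = "b1", chrom = "chr1", start = 10, end = 20)
  expect_equal(nrow(overlap_query(a, b)), 0)
  # plain overlap arithmetic
  a <- data.frame(id = "a1", chrom = "chr1", start = 100, end = 200)
  b <- data.frame(id = "b1", chrom = "chr1", start = 150, end = 250)
  ov <- overlap_query(a, b)
  expect_equal(ov$overlap_bp, 50)

  set.seed(11)
  a <- random_intervals(200, prefix = "a")
  b <- random_intervals(200, prefix = "b")
  got <- sort_pairs(overlap_query(a, b))
  want <- sort_pairs(oracle_overlaps(a, b))
  expect_equal(got, want)
  # symmetry: swapping arguments transposes the pair set
  rev <- sort_pairs(overlap_query(b, a))
  expect_equal(rev$a_id, want[order(want$b_id, want$a_id), "b_id"])
  # self-overlap contains every self pair
  self <- overlap_query(a, a)
  expect_true(all(a$id %in% self$a_id[self$a_id == self$b_id]))
  # min_overlap filters
  got5 <- sort_pairs(overlap_query(a, b, min_overlap = 50))
  want5 <- sort_pairs(oracle_overlaps(a, b, min_overlap = 50))
  expect_equal(got5, want5)
  expect_error(overlap_query(a, b, min_overlap = 0), "min_overlap")
})

test_that("nearest_tss matches the exhaustive oracle including ties", {
  ann <- tiny_annotation()
  # midpoint exactly at a TSS
  pk <- data.frame(id = "p1", chrom = "chr1", start = 990, end = 1010)
  nt <- nearest_tss(pk, ann)
  expect_equal(nt$gene_id, "gA")
  expect_equal(nt$distance, 0)
  # gene-free chromosome -> NA with warning
  pk2 <- data.frame(id = "p2", chrom = "chrX", start = 0, end = 10)
  expect_warning(nt2 <- nearest_tss(pk2, ann), "without genes")
  expect_true(is.na(nt2$gene_id))

  set.seed(13)
  ann2 <- random_annotation(25)
  peaks <- random_intervals(100, max_pos = 49000)
  got <- nearest_tss(peaks, ann2)
  want <- oracle_nearest_tss(peaks, ann2)
  expect_equal(got, want)
  # with a distance cutoff
  got2 <- nearest_tss(peaks, ann2, max_distance = 500)
  want2 <- oracle_nearest_tss(peaks, ann2, max_distance = 500)
  expect_equal(got2, want2)
  # exact tie between two genes resolves to the smaller id
  tie_ann <- genome_annotation(
    c(chr1 = 10000),
    data.frame(gene_id = c("gB", "gA"), chrom = "chr1",
               start = c(2000, 4000), end = c(2500, 4500),
               strand = "+", stringsAsFactors = FALSE))
  tie_pk <- data.frame(id = "t", chrom = "chr1", start = 2995, end = 3005)
  expect_equal(nearest_tss(tie_pk, tie_ann)$gene_id, "gA")
})

test_that("genomic feature assignment partitions peaks and matches the oracle", {
  ann <- tiny_annotation()
  # 300 bp upstream of a + strand TSS -> promoter
  pk <- data.frame(id = "p1", chrom = "chr1", start = 695, end = 705)
  expect_equal(assign_genomic_feature(pk, ann), "promoter")
  # inside an exon away from any promoter window
  pk2 <- data.frame(id = "p2", chrom = "chr1", start = 2595, end = 2605)
  expect_equal(assign_genomic_feature(pk2, ann), "exon")
  # gene-free chromosome -> intergenic
  pk3 <- data.frame(id = "p3", chrom = "chr2", start = 10000, end = 10100)
  expect_equal(assign_genomic_feature(pk3, ann), "intergenic")

  set.seed(17)
  ann2 <- random_annotation(20)
  peaks <- random_intervals(100, max_pos = 49000)
  got <- assign_genomic_feature(peaks, ann2)
  expect_equal(got, oracle_feature(peaks, ann2))
  # every peak gets exactly one label
  expect_length(got, nrow(peaks))
  expect_true(all(got %in% c("promoter", "exon", "intron", "intergenic")))
})

test_that("interval containers enforce their invariants", {
  expect_error(peak_set(data.frame(id = "p", chrom = "chr1",
                                   start = 10, end = 10)), "start < end")
  expect_error(peak_set(data.frame(id = c("p", "p"), chrom = "chr1",
                                   start = c(1, 5), end = c(4, 9))),
               "duplicate")
  ann <- tiny_annotation()
  expect_error(peak_set(data.frame(id = "p", chrom = "chr1",
                                   start = 1, end = 30000),
                        annotation = ann), "chromosome size")
  expect_error(genome_annotation(c(chr1 = 100),
                                 data.frame(gene_id = "g", chrom = "chr1",
                                            start = 10, end = 200,
                                            strand = "+")),
               "beyond chromosome")
})
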