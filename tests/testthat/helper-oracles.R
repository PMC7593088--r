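# Brute-force oracles and tiny fixture builders. Oracles are deliberately
# naive (all-pairs loops, explicit choose() sums) and independent of the
# implementation paths they check.

random_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 10000,
                             max_len = 200, prefix = "iv") {
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  len <- sample.int(max_len, n, replace = TRUE)
  df <- data.frame(id = sprintf("%s%03d", prefix, seq_len(n)),
                   chrom = sample(chroms, n, replace = TRUE),
                   start = start, end = start + len,
                   stringsAsFactors = FALSE)
  df[order(df$chrom, df$start, method = "radix"), , drop = FALSE]
}

# O(nm) all-pairs overlap oracle
oracle_overlaps <- function(a, b, min_overlap = 1) {
  out <- list()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] != b$chrom[j]) next
      ov <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
      if (ov >= min_overlap) {
        out[[length(out) + 1]] <- data.frame(
          a_id = a$id[i], b_id = b$id[j], overlap_bp = ov,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(a_id = character(), b_id = character(),
                      overlap_bp = numeric()))
  }
  do.call(rbind, out)
}

sort_pairs <- function(df) {
  df <- df[order(df$a_id, df$b_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# exhaustive nearest-TSS oracle with lexicographic tie-break
oracle_nearest_tss <- function(peaks, ann, max_distance = Inf) {
  genes <- ann$genes
  out <- data.frame(peak_id = peaks$id, gene_id = NA_character_,
                    distance = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(peaks))) {
    mid <- floor((peaks$start[i] + peaks$end[i]) / 2)
    g <- genes[genes$chrom == peaks$chrom[i], , drop = FALSE]
    if (nrow(g) == 0) next
    d <- abs(mid - g$tss)
    best <- min(d)
    if (best > max_distance) next
    cand <- g$gene_id[d == best]
    gid <- min(cand)
    out$gene_id[i] <- gid
    out$distance[i] <- mid - g$tss[match(gid, g$gene_id)]
  }
  out
}

# rule-by-rule genomic feature oracle
oracle_feature <- function(peaks, ann, upstream = 1000, downstream = 100) {
  genes <- ann$genes
  exons <- ann$exons
  vapply(seq_len(nrow(peaks)), function(i) {
    mid <- floor((peaks$start[i] + peaks$end[i]) / 2)
    g <- genes[genes$chrom == peaks$chrom[i], , drop = FALSE]
    if (nrow(g) > 0) {
      lo <- ifelse(g$strand == "+", g$tss - upstream, g$tss - downstream)
      hi <- ifelse(g$strand == "+", g$tss + downstream, g$tss + upstream)
      if (any(mid >= lo & mid <= hi)) return("promoter")
      e <- exons[exons$chrom == peaks$chrom[i], , drop = FALSE]
      if (nrow(e) > 0 && any(mid >= e$start & mid < e$end)) return("exon")
      if (any(mid >= g$start & mid < g$end)) return("intron")
    }
    "intergenic"
  }, character(1))
}

# explicit choose() hypergeometric enumeration for a 2x2 table
oracle_fisher <- function(a, b, c, d) {
  m <- a + b
  n2 <- c + d
  k <- a + c
  support <- max(0, k - n2):min(k, m)
  probs <- choose(m, support) * choose(n2, k - support) / choose(m + n2, k)
  p_obs <- probs[match(a, support)]
  list(p_one_sided = sum(probs[support >= a]),
       p_two_sided = min(1, sum(probs[probs <= p_obs * (1 + 1e-7)])))
}

# explicit binomial upper-tail sum
oracle_binom_upper <- function(k, n, q) {
  if (k == 0) return(1)
  i <- k:n
  sum(choose(n, i) * q^i * (1 - q)^(n - i))
}

# hand step-up BH oracle
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(1, adj)
  out
}

# small deterministic annotation: two chromosomes, three genes with exons
tiny_annotation <- function() {
  genes <- data.frame(
    gene_id = c("gA", "gB", "gC"),
    chrom = c("chr1", "chr1", "chr2"),
    start = c(1000, 6000, 2000),
    end = c(3000, 9000, 5000),
    strand = c("+", "-", "+"),
    stringsAsFactors = FALSE)
  exons <- data.frame(
    gene_id = c("gA", "gA", "gB", "gC"),
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    start = c(1000, 2500, 8000, 2000),
    end = c(1400, 3000, 9000, 2600),
    stringsAsFactors = FALSE)
  genome_annotation(c(chr1 = 20000, chr2 = 20000), genes, exons)
}

random_annotation <- function(n_genes = 20, chroms = c("chr1", "chr2"),
                              size = 50000) {
  start <- sample.int(size - 3000, n_genes, replace = TRUE)
  len <- sample(500:2000, n_genes, replace = TRUE)
  genes <- data.frame(
    gene_id = sprintf("g%03d", seq_len(n_genes)),
    chrom = sample(chroms, n_genes, replace = TRUE),
    start = start, end = start + len,
    strand = sample(c("+", "-"), n_genes, replace = TRUE),
    stringsAsFactors = FALSE)
  genome_annotation(stats::setNames(rep(size, length(chroms)), chroms), genes)
}

random_dna <- function(n, len_range = c(30, 80)) {
  lens <- len_range[1] +
    sample.int(len_range[2] - len_range[1] + 1, n, replace = TRUE) - 1L
  vapply(lens, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1))
}

dinuc_counts <- function(s) {
  ch <- strsplit(s, "")[[1]]
  if (length(ch) < 2) return(table(factor(character(), levels = "AA")))
  table(paste0(ch[-length(ch)], ch[-1]))
}

# scaled-down profile overrides for fast end-to-end tests
small_epigenome_overrides <- function() {
  list(genome = list(n_genes = 400),
       peaks = list(n_chip = 500, n_atac = 1000))
}
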