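# Interval arithmetic over 0-based half-open records. The heavy lifting is
# delegated to IRanges/GenomicRanges; these wrappers fix the coordinate
# convention, the sortedness contract and deterministic tie-breaking.

as_intervals <- function(x) {
  if (inherits(x, "PeakSet")) return(x$peaks)
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "chrom", "start", "end") %in% names(x)))
  x$id <- as.character(x$id)
  x$chrom <- as.character(x$chrom)
  validate_intervals(x)
  x
}

# half-open [start, end) -> 1-based closed IRanges
intervals_to_granges <- function(df, seqlevels = NULL) {
  if (is.null(seqlevels)) seqlevels <- unique(df$chrom)
  GenomicRanges::GRanges(
    factor(df$chrom, levels = seqlevels),
    IRanges::IRanges(start = df$start + 1, end = df$end))
}

check_sorted <- function(df, what) {
  ord <- order(df$chrom, df$start, method = "radix")
  if (!identical(ord, seq_len(nrow(df)))) {
    warning(what, " intervals not sorted by (chrom, start); sorting internally")
    df <- df[ord, , drop = FALSE]
  }
  df
}

#' All overlapping interval pairs between two collections
#'
#' Returns exactly the pairs on the same chromosome whose overlap length is at
#' least `min_overlap` bp, with
#' `overlap_bp = min(end_a, end_b) - max(start_a, start_b)`. Half-open
#' adjacency (`[0,10)` vs `[10,20)`) does not overlap.
#'
#' @param a,b interval collections: a [peak_set()] or a data.frame with
#'   columns `id`, `chrom`, `start`, `end`, sorted by (chrom, start).
#'   Unsorted input is sorted internally with a warning.
#' @param min_overlap minimum overlap in bp (>= 1).
#' @return data.frame with columns `a_id`, `b_id`, `overlap_bp`, ordered by
#'   (a_id position, b_id position).
#' @export
overlap_query <- function(a, b, min_overlap = 1L) {
  if (min_overlap < 1) stop("min_overlap must be >= 1")
  a <- check_sorted(as_intervals(a), "a")
  b <- check_sorted(as_intervals(b), "b")
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(data.frame(a_id = character(), b_id = character(),
                      overlap_bp = numeric()))
  }
  lv <- union(unique(a$chrom), unique(b$chrom))
  gra <- intervals_to_granges(a, lv)
  grb <- intervals_to_granges(b, lv)
  hits <- GenomicRanges::findOverlaps(gra, grb,
                                      minoverlap = as.integer(min_overlap))
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ov <- pmin(a$end[qi], b$end[si]) - pmax(a$start[qi], b$start[si])
  data.frame(a_id = a$id[qi], b_id = b$id[si], overlap_bp = ov,
             stringsAsFactors = FALSE)
}

#' Nearest transcription start site for each peak
#'
#' Distance is measured from the peak midpoint (`floor((start+end)/2)`) to
#' each gene's TSS. Peaks whose nearest TSS is farther than `max_distance`
#' (or that lie on a gene-free chromosome, with a warning) get `NA`.
#' Distance ties are broken by the lexicographically smaller gene id. The
#' signed distance is `midpoint - tss` (positive when the midpoint lies
#' 3' of the TSS in genome coordinates).
#'
#' @param peaks a [peak_set()] or interval data.frame.
#' @param annotation a [genome_annotation()].
#' @param max_distance maximum |distance| in bp.
#' @return data.frame with columns `peak_id`, `gene_id`, `distance`.
#' @export
nearest_tss <- function(peaks, annotation, max_distance = Inf) {
  stopifnot(inherits(annotation, "GenomeAnnotation"))
  p <- as_intervals(peaks)
  genes <- annotation$genes
  if (nrow(genes) == 0) stop("annotation has no genes")
  mid <- floor((p$start + p$end) / 2)
  out_gene <- rep(NA_character_, nrow(p))
  out_dist <- rep(NA_real_, nrow(p))
  gene_free <- setdiff(unique(p$chrom), unique(genes$chrom))
  if (length(gene_free) > 0) {
    warning("peak chromosome(s) without genes: ",
            paste(gene_free, collapse = ", "))
  }
  for (ch in intersect(unique(p$chrom), unique(genes$chrom))) {
    gi <- genes[genes$chrom == ch, , drop = FALSE]
    # sort by (tss, gene_id) so equal-TSS blocks start with the smallest id
    gi <- gi[order(gi$tss, gi$gene_id, method = "radix"), , drop = FALSE]
    tss <- gi$tss
    pi_idx <- which(p$chrom == ch)
    m <- mid[pi_idx]
    lo <- findInterval(m, tss)          # last tss <= m (0 if none)
    hi <- pmin(lo + 1L, length(tss))
    lo <- pmax(lo, 1L)
    d_lo <- abs(m - tss[lo])
    d_hi <- abs(m - tss[hi])
    best <- pmin(d_lo, d_hi)
    for (k in seq_along(pi_idx)) {
      bd <- best[k]
      if (bd > max_distance) next
      cand <- which(tss == m[k] - bd | tss == m[k] + bd)
      gid <- min(gi$gene_id[cand])
      out_gene[pi_idx[k]] <- gid
      out_dist[pi_idx[k]] <- m[k] - gi$tss[match(gid, gi$gene_id)]
    }
  }
  data.frame(peak_id = p$id, gene_id = out_gene, distance = out_dist,
             stringsAsFactors = FALSE)
}

#' Assign each peak to a genomic feature class
#'
#' Evaluated at the peak midpoint, with precedence
#' promoter > exon > intron > intergenic, so the labels partition the peak
#' set. The promoter window is strand-aware: `upstream` bp upstream to
#' `downstream` bp downstream of the TSS (midpoint within the window,
#' inclusive).
#'
#' @param peaks a [peak_set()] or interval data.frame.
#' @param annotation a [genome_annotation()].
#' @param upstream,downstream promoter window (bp).
#' @return character vector of labels in peak order, one of `"promoter"`,
#'   `"exon"`, `"intron"`, `"intergenic"`.
#' @export
assign_genomic_feature <- function(peaks, annotation,
                                   upstream = 1000L, downstream = 100L) {
  stopifnot(inherits(annotation, "GenomeAnnotation"))
  p <- as_intervals(peaks)
  n <- nrow(p)
  if (n == 0) return(character(0))
  mid <- floor((p$start + p$end) / 2)
  midgr <- GenomicRanges::GRanges(p$chrom, IRanges::IRanges(mid + 1, mid + 1))
  genes <- annotation$genes
  label <- rep("intergenic", n)
  if (nrow(genes) > 0) {
    # gene bodies
    bodygr <- intervals_to_granges(genes)
    in_body <- IRanges::overlapsAny(midgr, bodygr)
    label[in_body] <- "intron"
    # exons
    if (nrow(annotation$exons) > 0) {
      exgr <- intervals_to_granges(annotation$exons)
      label[IRanges::overlapsAny(midgr, exgr)] <- "exon"
    }
    # promoter windows (midpoint within [tss-upstream, tss+downstream],
    # orientation following strand)
    pstart <- ifelse(genes$strand == "+", genes$tss - upstream,
                     genes$tss - downstream)
    pend <- ifelse(genes$strand == "+", genes$tss + downstream,
                   genes$tss + upstream)
    pstart <- pmax(pstart, 0)
    promgr <- GenomicRanges::GRanges(genes$chrom,
                                     IRanges::IRanges(pstart + 1, pend + 1))
    label[IRanges::overlapsAny(midgr, promgr)] <- "promoter"
  }
  label
}
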