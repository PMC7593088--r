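#' Construct a peak set
#'
#' A `PeakSet` holds genomic intervals of binding (ChIP) or accessibility
#' (ATAC) enrichment in the 0-based half-open (BED) convention, together with
#' optional per-sample read counts. Peaks are kept sorted by (chrom, start)
#' and identifiers must be unique.
#'
#' @param peaks data.frame with columns `id`, `chrom`, `start`, `end` and
#'   optionally `strand`, `summit_offset`, `score`. Coordinates are 0-based
#'   half-open.
#' @param name label for the set.
#' @param assay one of `"CHIP"`, `"ATAC"`.
#' @param genotype genotype label (e.g. `"WT"`, `"HET"`, `"R456G"`), optional.
#' @param day differentiation day, optional integer.
#' @param counts optional numeric matrix of non-negative integer read counts,
#'   rows named by peak id, columns by sample.
#' @param annotation optional [genome_annotation()]; when supplied, peaks are
#'   checked against chromosome bounds.
#' @return An object of class `PeakSet`.
#' @export
peak_set <- function(peaks, name = "peaks", assay = c("CHIP", "ATAC"),
                     genotype = NA_character_, day = NA_integer_,
                     counts = NULL, annotation = NULL) {
  assay <- match.arg(assay)
  peaks <- as.data.frame(peaks, stringsAsFactors = FALSE)
  required <- c("id", "chrom", "start", "end")
  missing_cols <- setdiff(required, names(peaks))
  if (length(missing_cols) > 0) {
    stop("peaks is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  n <- nrow(peaks)
  if (!"strand" %in% names(peaks)) peaks$strand <- rep(".", n)
  if (!"summit_offset" %in% names(peaks)) {
    peaks$summit_offset <- rep(NA_integer_, n)
  }
  if (!"score" %in% names(peaks)) peaks$score <- rep(NA_real_, n)
  peaks$id <- as.character(peaks$id)
  peaks$chrom <- as.character(peaks$chrom)
  validate_intervals(peaks)
  if (anyDuplicated(peaks$id)) {
    stop("duplicate peak ids: ",
         paste(utils::head(unique(peaks$id[duplicated(peaks$id)]), 3),
               collapse = ", "))
  }
  ord <- order(peaks$chrom, peaks$start, peaks$end, peaks$id, method = "radix")
  peaks <- peaks[ord, c("id", "chrom", "start", "end", "strand",
                        "summit_offset", "score")]
  rownames(peaks) <- NULL
  if (!is.null(counts)) {
    counts <- as.matrix(counts)
    if (is.null(rownames(counts)) || !setequal(rownames(counts), peaks$id)) {
      stop("counts rownames must match peak ids exactly")
    }
    if (any(counts < 0) || any(counts != round(counts))) {
      stop("counts must be non-negative integers")
    }
    counts <- counts[peaks$id, , drop = FALSE]
  }
  if (!is.null(annotation)) {
    check_against_annotation(peaks, annotation)
  }
  structure(
    list(name = name, assay = assay, genotype = genotype, day = day,
         peaks = peaks, counts = counts),
    class = "PeakSet"
  )
}

validate_intervals <- function(df) {
  if (any(is.na(df$start)) || any(is.na(df$end))) {
    stop("interval coordinates contain NA")
  }
  bad <- which(df$start < 0 | df$start >= df$end)
  if (length(bad) > 0) {
    stop("invalid interval (need 0 <= start < end) at record ", bad[1],
         ": [", df$start[bad[1]], ",", df$end[bad[1]], ")")
  }
  if (any(!nzchar(df$chrom))) stop("empty chromosome name")
  invisible(TRUE)
}

check_against_annotation <- function(df, annotation) {
  stopifnot(inherits(annotation, "GenomeAnnotation"))
  sizes <- annotation$chrom_sizes
  unknown <- setdiff(unique(df$chrom), names(sizes))
  if (length(unknown) > 0) {
    stop("chromosome(s) absent from annotation: ",
         paste(unknown, collapse = ", "))
  }
  if (any(df$end > sizes[df$chrom])) {
    stop("interval end exceeds chromosome size")
  }
  invisible(TRUE)
}

#' @export
print.PeakSet <- function(x, ...) {
  cat(sprintf("PeakSet '%s' (%s%s%s): %d peaks on %d chromosome(s)\n",
              x$name, x$assay,
              if (is.na(x$genotype)) "" else paste0(", ", x$genotype),
              if (is.na(x$day)) "" else paste0(", day ", x$day),
              nrow(x$peaks), length(unique(x$peaks$chrom))))
  if (!is.null(x$counts)) {
    cat("  counts: ", ncol(x$counts), " sample(s): ",
        paste(colnames(x$counts), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Construct a genome annotation
#'
#' Chromosome sizes plus gene models (gene body, strand, TSS, exons). The TSS
#' is `start` on the + strand and `end - 1` on the - strand, in 0-based
#' half-open coordinates.
#'
#' @param chrom_sizes named numeric vector of chromosome lengths (bp).
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` and optionally `symbol`.
#' @param exons optional data.frame with columns `gene_id`, `chrom`, `start`,
#'   `end`; exons must lie within their gene body and not overlap within a
#'   gene.
#' @return An object of class `GenomeAnnotation`.
#' @export
genome_annotation <- function(chrom_sizes, genes, exons = NULL) {
  stopifnot(!is.null(names(chrom_sizes)), all(chrom_sizes > 0))
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  req <- c("gene_id", "chrom", "start", "end", "strand")
  missing_cols <- setdiff(req, names(genes))
  if (length(missing_cols) > 0) {
    stop("genes is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!"symbol" %in% names(genes)) genes$symbol <- genes$gene_id
  genes$gene_id <- as.character(genes$gene_id)
  genes$chrom <- as.character(genes$chrom)
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene ids")
  if (!all(genes$strand %in% c("+", "-"))) {
    stop("gene strand must be '+' or '-'")
  }
  validate_intervals(genes)
  unknown <- setdiff(unique(genes$chrom), names(chrom_sizes))
  if (length(unknown) > 0) {
    stop("gene chromosome(s) absent from chrom_sizes: ",
         paste(unknown, collapse = ", "))
  }
  if (any(genes$end > chrom_sizes[genes$chrom])) {
    stop("gene extends beyond chromosome bound")
  }
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1)
  ord <- order(genes$chrom, genes$start, genes$gene_id, method = "radix")
  genes <- genes[ord, c("gene_id", "symbol", "chrom", "start", "end",
                        "strand", "tss")]
  rownames(genes) <- NULL
  if (!is.null(exons)) {
    exons <- as.data.frame(exons, stringsAsFactors = FALSE)
    stopifnot(all(c("gene_id", "chrom", "start", "end") %in% names(exons)))
    exons$gene_id <- as.character(exons$gene_id)
    validate_intervals(exons)
    orphans <- setdiff(unique(exons$gene_id), genes$gene_id)
    if (length(orphans) > 0) {
      stop("exon(s) without parent gene: ", paste(orphans, collapse = ", "))
    }
    gidx <- match(exons$gene_id, genes$gene_id)
    if (any(exons$start < genes$start[gidx] | exons$end > genes$end[gidx])) {
      stop("exon outside its gene body")
    }
    ord <- order(exons$gene_id, exons$start, method = "radix")
    exons <- exons[ord, c("gene_id", "chrom", "start", "end")]
    # non-overlap within each gene
    same_gene <- exons$gene_id[-1] == exons$gene_id[-nrow(exons)]
    if (nrow(exons) > 1 &&
        any(same_gene & exons$start[-1] < exons$end[-nrow(exons)])) {
      stop("overlapping exons within a gene")
    }
    rownames(exons) <- NULL
  } else {
    exons <- data.frame(gene_id = character(), chrom = character(),
                        start = numeric(), end = numeric())
  }
  structure(list(chrom_sizes = chrom_sizes, genes = genes, exons = exons),
            class = "GenomeAnnotation")
}

#' @export
print.GenomeAnnotation <- function(x, ...) {
  cat(sprintf("GenomeAnnotation: %d chromosome(s) (%.1f Mb), %d gene(s), %d exon(s)\n",
              length(x$chrom_sizes), sum(x$chrom_sizes) / 1e6,
              nrow(x$genes), nrow(x$exons)))
  invisible(x)
}

#' Construct a count table
#'
#' Rows are features (peaks or genes), columns are samples with condition
#' labels. Library sizes default to column sums.
#'
#' @param counts numeric matrix of non-negative integer counts with row and
#'   column names.
#' @param condition character/factor of length `ncol(counts)` assigning each
#'   sample to a condition.
#' @param lib_sizes optional positive library sizes per sample.
#' @return An object of class `CountTable`.
#' @export
count_table <- function(counts, condition, lib_sizes = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have row and column names")
  }
  if (any(counts < 0)) stop("counts must be non-negative")
  condition <- as.factor(condition)
  if (length(condition) != ncol(counts)) {
    stop("condition must have one entry per sample column")
  }
  if (any(table(condition) < 1)) stop("each condition needs >= 1 sample")
  if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
  lib_sizes <- as.numeric(lib_sizes)
  if (length(lib_sizes) != ncol(counts) || any(lib_sizes <= 0)) {
    stop("library sizes must be positive, one per sample")
  }
  names(lib_sizes) <- colnames(counts)
  names(condition) <- colnames(counts)
  structure(list(counts = counts, condition = condition,
                 lib_sizes = lib_sizes),
            class = "CountTable")
}

#' @export
print.CountTable <- function(x, ...) {
  cat(sprintf("CountTable: %d feature(s) x %d sample(s); conditions: %s\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s(n=%d)", levels(x$condition),
                            table(x$condition)), collapse = ", ")))
  invisible(x)
}
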