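#' Read peaks from BED6 or ENCODE narrowPeak
#'
#' Coordinates are preserved in the file's native 0-based half-open
#' convention. For narrowPeak the 10th column is mapped to `summit_offset`
#' (`-1` in the file becomes `NA`). Records with name `"."` receive
#' auto-generated ids `peak_1`, `peak_2`, ... in file order.
#'
#' @param path input file.
#' @param format `"BED6"` or `"narrowPeak"`.
#' @param ... passed to [peak_set()] (e.g. `name`, `assay`, `genotype`).
#' @return A [peak_set()] object.
#' @export
read_peaks <- function(path, format = c("BED6", "narrowPeak"), ...) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  ncol_expected <- if (format == "BED6") 6L else 10L
  if (length(lines) == 0) {
    return(peak_set(data.frame(id = character(), chrom = character(),
                               start = numeric(), end = numeric()), ...))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != ncol_expected)
  if (length(bad) > 0) {
    stop("malformed ", format, " line ", bad[1], " in ", path,
         ": expected ", ncol_expected, " fields, found ", nf[bad[1]])
  }
  m <- matrix(unlist(fields), ncol = ncol_expected, byrow = TRUE)
  start <- suppressWarnings(as.numeric(m[, 2]))
  end <- suppressWarnings(as.numeric(m[, 3]))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0) {
    stop("malformed ", format, " line ", bad[1], " in ", path,
         ": non-numeric coordinates")
  }
  bad <- which(start >= end | start < 0)
  if (length(bad) > 0) {
    stop("invalid interval at line ", bad[1], " in ", path,
         ": start >= end or start < 0")
  }
  ids <- m[, 4]
  auto <- ids == "."
  if (any(auto)) ids[auto] <- paste0("peak_", which(auto))
  if (anyDuplicated(ids[!auto])) {
    stop("duplicate explicit peak ids in ", path, ": ",
         paste(utils::head(unique(ids[!auto][duplicated(ids[!auto])]), 3),
               collapse = ", "))
  }
  df <- data.frame(id = ids, chrom = m[, 1], start = start, end = end,
                   strand = m[, 6],
                   score = suppressWarnings(as.numeric(m[, 5])),
                   stringsAsFactors = FALSE)
  if (format == "narrowPeak") {
    summit <- suppressWarnings(as.integer(m[, 10]))
    summit[!is.na(summit) & summit < 0] <- NA_integer_
    df$summit_offset <- summit
    df$signal <- suppressWarnings(as.numeric(m[, 7]))
  }
  peak_set(df, ...)
}

#' Write peaks to BED6 or ENCODE narrowPeak
#'
#' Output is sorted by (chrom, start) and deterministic for a fixed peak set.
#' Missing scores are written as 0; in narrowPeak a missing summit offset is
#' written as -1 and signal/p/q columns as 0/-1/-1.
#'
#' @param peakset a [peak_set()] object.
#' @param path output file.
#' @param format `"BED6"` or `"narrowPeak"`.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peakset, path, format = c("BED6", "narrowPeak")) {
  format <- match.arg(format)
  stopifnot(inherits(peakset, "PeakSet"))
  p <- peakset$peaks
  score <- ifelse(is.na(p$score), 0, p$score)
  strand <- ifelse(p$strand %in% c("+", "-"), p$strand, ".")
  base <- paste(p$chrom, format_coord(p$start), format_coord(p$end), p$id,
                format(score, trim = TRUE, scientific = FALSE), strand,
                sep = "\t")
  if (format == "narrowPeak") {
    summit <- ifelse(is.na(p$summit_offset), -1L, as.integer(p$summit_offset))
    base <- paste(base, "0", "-1", "-1", summit, sep = "\t")
  }
  con <- file(path, "wb")
  on.exit(close(con))
  if (length(base) > 0) writeLines(base, con)
  invisible(path)
}

format_coord <- function(x) format(x, trim = TRUE, scientific = FALSE)

#' Read a genome annotation from GTF-lite or a gene-model TSV
#'
#' GTF-lite means GTF lines whose feature is `gene` or `exon`, carrying a
#' `gene_id` attribute; 1-based inclusive GTF coordinates are converted to
#' the internal 0-based half-open convention on read. The TSV dialect has
#' columns `gene_id`, `chrom`, `start`, `end`, `strand` (0-based half-open)
#' and optionally `symbol`.
#'
#' @param path input file.
#' @param format `"GTF"` or `"TSV"`.
#' @param chrom_sizes named vector of chromosome lengths; if `NULL`, sizes
#'   are inferred as the maximum gene end per chromosome.
#' @return A [genome_annotation()] object.
#' @export
read_gene_annotation <- function(path, format = c("GTF", "TSV"),
                                 chrom_sizes = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "TSV") {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    genes <- df
    exons <- NULL
  } else {
    lines <- readLines(path)
    keep <- !grepl("^#", lines) & nzchar(lines)
    lines <- lines[keep]
    lineno <- which(keep)
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    bad <- which(nf != 9L)
    if (length(bad) > 0) {
      stop("malformed GTF line ", lineno[bad[1]], " in ", path,
           ": expected 9 fields, found ", nf[bad[1]])
    }
    m <- matrix(unlist(fields), ncol = 9L, byrow = TRUE)
    feature <- m[, 3]
    sel <- feature %in% c("gene", "exon")
    m <- m[sel, , drop = FALSE]
    lineno <- lineno[sel]
    start1 <- suppressWarnings(as.numeric(m[, 4]))
    end1 <- suppressWarnings(as.numeric(m[, 5]))
    bad <- which(is.na(start1) | is.na(end1) | start1 < 1 | end1 < start1)
    if (length(bad) > 0) {
      stop("gene/exon without valid coordinates at GTF line ",
           lineno[bad[1]], " in ", path)
    }
    gene_id <- sub('.*gene_id "([^"]+)".*', "\\1", m[, 9])
    bad <- which(gene_id == m[, 9])
    if (length(bad) > 0) {
      stop("missing gene_id attribute at GTF line ", lineno[bad[1]],
           " in ", path)
    }
    # GTF 1-based inclusive -> 0-based half-open
    df <- data.frame(gene_id = gene_id, chrom = m[, 1], start = start1 - 1,
                     end = end1, strand = m[, 7], feature = m[, 3],
                     stringsAsFactors = FALSE)
    genes <- df[df$feature == "gene",
                c("gene_id", "chrom", "start", "end", "strand")]
    exons <- df[df$feature == "exon", c("gene_id", "chrom", "start", "end")]
    if (nrow(exons) == 0) exons <- NULL
    orphan <- if (is.null(exons)) character() else
      setdiff(unique(exons$gene_id), genes$gene_id)
    if (length(orphan) > 0) {
      stop("exon(s) without parent gene in ", path, ": ",
           paste(orphan, collapse = ", "))
    }
  }
  if (is.null(chrom_sizes)) {
    chrom_sizes <- tapply(genes$end, genes$chrom, max)
    chrom_sizes <- stats::setNames(as.numeric(chrom_sizes), names(chrom_sizes))
  }
  genome_annotation(chrom_sizes, genes, exons)
}

#' Write a genome annotation as GTF
#'
#' Internal 0-based half-open coordinates are converted to the 1-based
#' inclusive GTF convention on write.
#'
#' @param annotation a [genome_annotation()] object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gene_annotation <- function(annotation, path) {
  stopifnot(inherits(annotation, "GenomeAnnotation"))
  g <- annotation$genes
  gl <- paste(g$chrom, "pioneerscan", "gene", format_coord(g$start + 1),
              format_coord(g$end), ".", g$strand, ".",
              sprintf('gene_id "%s";', g$gene_id), sep = "\t")
  e <- annotation$exons
  el <- character(0)
  if (nrow(e) > 0) {
    strand <- annotation$genes$strand[match(e$gene_id,
                                            annotation$genes$gene_id)]
    el <- paste(e$chrom, "pioneerscan", "exon", format_coord(e$start + 1),
                format_coord(e$end), ".", strand, ".",
                sprintf('gene_id "%s";', e$gene_id), sep = "\t")
  }
  out <- c(gl, el)
  key <- c(g$chrom, e$chrom)
  pos <- c(g$start, e$start)
  out <- out[order(key, pos, method = "radix")]
  writeLines(out, path)
  invisible(path)
}

#' Read a patient cohort table
#'
#' Expected TSV columns: `patient_id`, `variant_class` (`LoF` or `missense`),
#' `residue_position` (integer or `NA` for non-coding/splice), and logical
#' flags `extracardiac`, `pa_cdh`, `neuro`.
#'
#' @param path input TSV.
#' @return A validated cohort data.frame of class `CohortTable`.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  as_cohort_table(df)
}

#' Validate a cohort data.frame
#'
#' @param df data.frame with the columns documented in [read_cohort()].
#' @param protein_length protein length in amino acids; residue positions
#'   must not exceed it.
#' @return `df` with class `CohortTable` prepended.
#' @export
as_cohort_table <- function(df, protein_length = 595L) {
  req <- c("patient_id", "variant_class", "residue_position",
           "extracardiac", "pa_cdh", "neuro")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0) {
    stop("cohort is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) == 0) stop("empty cohort")
  if (anyDuplicated(df$patient_id)) stop("duplicate patient ids")
  if (!all(df$variant_class %in% c("LoF", "missense"))) {
    bad <- which(!df$variant_class %in% c("LoF", "missense"))
    stop("unknown variant_class at row ", bad[1], ": ",
         df$variant_class[bad[1]])
  }
  for (fl in c("extracardiac", "pa_cdh", "neuro")) {
    df[[fl]] <- as.logical(df[[fl]])
    if (any(is.na(df[[fl]]))) stop("non-boolean values in flag ", fl)
  }
  pos <- df$residue_position
  if (any(!is.na(pos) & (pos < 1 | pos > protein_length))) {
    stop("residue_position outside 1..", protein_length)
  }
  attr(df, "protein_length") <- protein_length
  class(df) <- c("CohortTable", class(df))
  df
}

#' Write a cohort table as TSV
#' @param cohort a `CohortTable`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.table(as.data.frame(cohort), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
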