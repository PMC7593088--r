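# Open/closed chromatin classification of binding peaks by accessibility
# overlap, genomic-location summaries and genotype peak-set comparisons.

#' Classify binding peaks as open or closed chromatin
#'
#' A ChIP peak is OPEN when it overlaps at least one ATAC (accessibility)
#' peak by `min_overlap` bp or more, otherwise CLOSED. The reported
#' `overlap_bp` is the largest single-peak overlap (0 for CLOSED).
#'
#' @param chip a [peak_set()] of binding peaks (the set being classified).
#' @param atac a [peak_set()] of accessibility peaks.
#' @param min_overlap minimum overlap in bp.
#' @return An object of class `ChromatinClassification`: list with `per_peak`
#'   (data.frame `peak_id`, `state`, `overlap_bp`), `n_total`, `n_open`,
#'   `n_closed`, `frac_open`, `frac_closed`, `min_overlap`.
#' @export
classify_open_closed <- function(chip, atac, min_overlap = 1L) {
  stopifnot(inherits(chip, "PeakSet"), inherits(atac, "PeakSet"))
  if (nrow(chip$peaks) == 0) stop("empty ChIP peak set: nothing to classify")
  ov <- overlap_query(chip$peaks, atac$peaks, min_overlap = min_overlap)
  best <- numeric(nrow(chip$peaks))
  names(best) <- chip$peaks$id
  if (nrow(ov) > 0) {
    mx <- tapply(ov$overlap_bp, ov$a_id, max)
    best[names(mx)] <- mx
  }
  state <- ifelse(best >= min_overlap, "OPEN", "CLOSED")
  per_peak <- data.frame(peak_id = chip$peaks$id, state = state,
                         overlap_bp = as.numeric(best),
                         stringsAsFactors = FALSE, row.names = NULL)
  n_total <- nrow(per_peak)
  n_open <- sum(state == "OPEN")
  structure(list(per_peak = per_peak, n_total = n_total, n_open = n_open,
                 n_closed = n_total - n_open, frac_open = n_open / n_total,
                 frac_closed = 1 - n_open / n_total,
                 min_overlap = as.integer(min_overlap)),
            class = "ChromatinClassification")
}

#' @export
print.ChromatinClassification <- function(x, ...) {
  cat(sprintf("ChromatinClassification: %d peaks, %d OPEN (%.1f%%), %d CLOSED (%.1f%%)\n",
              x$n_total, x$n_open, 100 * x$frac_open,
              x$n_closed, 100 * x$frac_closed))
  invisible(x)
}

#' Genomic-location distribution of classified peaks
#'
#' Cross-tabulates chromatin state against genomic feature (promoter, exon,
#' intron, intergenic; assigned at the peak midpoint) and reports per-state
#' fractions, which sum to 1 within each state.
#'
#' @param classification a [classify_open_closed()] result.
#' @param peakset the [peak_set()] the classification was derived from.
#' @param annotation a [genome_annotation()].
#' @param ... promoter window parameters for [assign_genomic_feature()].
#' @return data.frame with columns `state`, `feature`, `n`, `fraction`.
#' @export
location_distribution <- function(classification, peakset, annotation, ...) {
  stopifnot(inherits(classification, "ChromatinClassification"),
            inherits(peakset, "PeakSet"))
  if (!setequal(classification$per_peak$peak_id, peakset$peaks$id)) {
    stop("classification and peak set cover different peak ids")
  }
  feat <- assign_genomic_feature(peakset, annotation, ...)
  state <- classification$per_peak$state[
    match(peakset$peaks$id, classification$per_peak$peak_id)]
  lv <- c("promoter", "exon", "intron", "intergenic")
  tab <- table(state = factor(state, c("OPEN", "CLOSED")),
               feature = factor(feat, lv))
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(out)[names(out) == "Freq"] <- "n"
  out$state <- as.character(out$state)
  out$feature <- as.character(out$feature)
  per_state <- as.numeric(tapply(out$n, out$state, sum)[out$state])
  out$fraction <- ifelse(per_state > 0, out$n / per_state, 0)
  out <- out[order(out$state, match(out$feature, lv)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compare two genotypes' peak sets using differential-occupancy calls
#'
#' LOST peaks are those called `REDUCED` (present in the reference, diminished
#' in the other genotype); GAINED are those called `INCREASED`. Fractions use
#' the figure-style denominators: `|LOST| / |reference|` and
#' `|GAINED| / |other|`.
#'
#' @param reference,other [peak_set()] objects for the two genotypes.
#' @param diff_results data.frame from [call_differential_peaks()] covering
#'   the union peak set (columns `peak_id`, `call`).
#' @return An object of class `PeakSetComparison`: list with id vectors
#'   `lost`, `gained`, `shared`, counts, and `lost_frac`, `gained_frac`.
#' @export
compare_genotype_peaksets <- function(reference, other, diff_results) {
  stopifnot(inherits(reference, "PeakSet"), inherits(other, "PeakSet"))
  stopifnot(all(c("peak_id", "call") %in% names(diff_results)))
  union_ids <- union(reference$peaks$id, other$peaks$id)
  unknown <- setdiff(diff_results$peak_id, union_ids)
  if (length(unknown) > 0) {
    stop("diff_results cover unknown peak ids: ",
         paste(utils::head(unknown, 3), collapse = ", "))
  }
  reduced <- diff_results$peak_id[diff_results$call == "REDUCED"]
  increased <- diff_results$peak_id[diff_results$call == "INCREASED"]
  lost <- intersect(reference$peaks$id, reduced)
  gained <- intersect(other$peaks$id, increased)
  shared <- setdiff(union_ids, union(lost, gained))
  structure(list(lost = lost, gained = gained, shared = shared,
                 n_lost = length(lost), n_gained = length(gained),
                 n_reference = nrow(reference$peaks),
                 n_other = nrow(other$peaks),
                 lost_frac = length(lost) / nrow(reference$peaks),
                 gained_frac = length(gained) / nrow(other$peaks),
                 reference = reference$name, other = other$name),
            class = "PeakSetComparison")
}

#' @export
print.PeakSetComparison <- function(x, ...) {
  cat(sprintf("PeakSetComparison %s vs %s: %d LOST (%.1f%% of %d), %d GAINED (%.1f%% of %d)\n",
              x$reference, x$other, x$n_lost, 100 * x$lost_frac,
              x$n_reference, x$n_gained, 100 * x$gained_frac, x$n_other))
  invisible(x)
}

#' Chromatin accessibility of differential (LOST/GAINED) peaks
#'
#' Overlaps the LOST and GAINED subsets with an accessibility peak set and
#' reports the fraction of each falling in open chromatin, together with the
#' open/closed peak-id subsets for downstream motif testing. The ATAC set is
#' an explicit argument: pair LOST peaks with the reference genotype's ATAC
#' data and GAINED peaks with the other genotype's (the pairing used for the
#' comparisons this reproduces).
#'
#' @param comparison a [compare_genotype_peaksets()] result.
#' @param peaks a [peak_set()] (or interval data.frame) holding coordinates
#'   for every LOST/GAINED peak id (typically the union peak set).
#' @param atac accessibility [peak_set()].
#' @param min_overlap minimum overlap in bp.
#' @return list with `frac_open_lost`, `frac_open_gained` (NA when the subset
#'   is empty) and per-subset id lists `lost_open`, `lost_closed`,
#'   `gained_open`, `gained_closed`.
#' @export
accessibility_of_differential_peaks <- function(comparison, peaks, atac,
                                                min_overlap = 1L) {
  stopifnot(inherits(comparison, "PeakSetComparison"))
  if (length(comparison$lost) == 0 && length(comparison$gained) == 0) {
    stop("comparison has no LOST and no GAINED peaks")
  }
  ivs <- as_intervals(peaks)
  split_open <- function(ids) {
    if (length(ids) == 0) {
      return(list(open = character(0), closed = character(0), frac = NA_real_))
    }
    sub <- ivs[ivs$id %in% ids, , drop = FALSE]
    if (nrow(sub) != length(ids)) {
      stop("peaks collection is missing coordinates for some differential ids")
    }
    sub <- sub[order(sub$chrom, sub$start, method = "radix"), , drop = FALSE]
    ov <- overlap_query(sub, atac$peaks, min_overlap = min_overlap)
    open <- intersect(ids, unique(ov$a_id))
    list(open = open, closed = setdiff(ids, open),
         frac = length(open) / length(ids))
  }
  l <- split_open(comparison$lost)
  g <- split_open(comparison$gained)
  list(frac_open_lost = l$frac, frac_open_gained = g$frac,
       lost_open = l$open, lost_closed = l$closed,
       gained_open = g$open, gained_closed = g$closed)
}
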