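# Headline integration: link closed-chromatin binding peaks to genes via
# nearest TSS and quantify the association between early closed-chromatin
# binding and later transcriptional activation.

#' Assign peaks to genes by nearest TSS within a window
#'
#' Each peak is assigned to the gene whose TSS is nearest to the peak
#' midpoint via [nearest_tss()]; peaks farther than `max_distance` from every
#' TSS remain unassigned and are counted.
#'
#' @param peaks a [peak_set()] or interval data.frame (typically the
#'   closed-chromatin binding subset).
#' @param annotation a [genome_annotation()].
#' @param max_distance association window in bp (default 50 kb).
#' @return list with `gene_map` (named list gene_id -> character vector of
#'   peak ids), `assignments` (data.frame `peak_id`, `gene_id`, `distance`),
#'   `n_assigned`, `n_unassigned`, `max_distance`.
#' @export
associate_peaks_to_genes <- function(peaks, annotation, max_distance = 5e4) {
  nt <- nearest_tss(peaks, annotation, max_distance = max_distance)
  assigned <- nt[!is.na(nt$gene_id), , drop = FALSE]
  gene_map <- split(assigned$peak_id, assigned$gene_id)
  list(gene_map = gene_map, assignments = nt,
       n_assigned = nrow(assigned),
       n_unassigned = nrow(nt) - nrow(assigned),
       max_distance = max_distance)
}

#' Pioneer-factor association statistics
#'
#' Given the differential-expression results between an early and a later
#' time point and a gene -> closed-chromatin-peak map, computes: the number
#' of differentially expressed (DE) genes, how many of them have at least one
#' assigned closed-chromatin binding peak (`n_assoc`, `frac_assoc`), and how
#' many of the associated genes increase at the later time point (`n_up`,
#' `frac_up`; call `UP`, not raw fold-change sign). `frac_up` is `NA`
#' (not computable) when no DE gene is associated.
#'
#' @param de_results data.frame from [differential_expression()].
#' @param closed_bound_gene_map named list gene_id -> peak ids, from
#'   [associate_peaks_to_genes()] on the closed-chromatin peak subset.
#' @return An object of class `PioneerAssociation`: list with `n_de`,
#'   `n_assoc`, `frac_assoc`, `n_up`, `frac_up` and a gene-level `evidence`
#'   table (gene_id, call, associated, peak_ids).
#' @export
pioneer_association_stats <- function(de_results, closed_bound_gene_map) {
  stopifnot(all(c("gene_id", "call") %in% names(de_results)))
  de <- de_results[de_results$call != "NS", , drop = FALSE]
  if (nrow(de) == 0) stop("empty DE set")
  assoc_genes <- names(closed_bound_gene_map)
  de$associated <- de$gene_id %in% assoc_genes
  n_de <- nrow(de)
  n_assoc <- sum(de$associated)
  n_up <- sum(de$associated & de$call == "UP")
  evidence <- data.frame(
    gene_id = de$gene_id, call = de$call, associated = de$associated,
    peak_ids = vapply(de$gene_id, function(g) {
      p <- closed_bound_gene_map[[g]]
      if (is.null(p)) "" else paste(p, collapse = ",")
    }, character(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(n_de = n_de, n_assoc = n_assoc,
                 frac_assoc = n_assoc / n_de,
                 n_up = n_up,
                 frac_up = if (n_assoc > 0) n_up / n_assoc else NA_real_,
                 evidence = evidence),
            class = "PioneerAssociation")
}

#' @export
print.PioneerAssociation <- function(x, ...) {
  cat(sprintf("PioneerAssociation: %d DE genes; %d associated with closed-chromatin binding (%.1f%%)",
              x$n_de, x$n_assoc, 100 * x$frac_assoc))
  if (!is.na(x$frac_up)) {
    cat(sprintf("; %d of those UP at the later time point (%.1f%%)",
                x$n_up, 100 * x$frac_up))
  }
  cat("\n")
  invisible(x)
}

#' Permutation test: is closed-chromatin binding enriched among DE genes?
#'
#' Permutes the DE label across all expressed genes `n_perm` times,
#' recomputing the associated fraction each time;
#' `p = (1 + #\{perm >= observed\}) / (n_perm + 1)`.
#'
#' @param association a [pioneer_association_stats()] result.
#' @param all_genes character vector of all expressed gene ids (the
#'   permutation universe).
#' @param closed_bound_gene_map as in [pioneer_association_stats()].
#' @param n_perm number of permutations (>= 100).
#' @param seed RNG seed.
#' @return list with `p`, `observed`, `perm_fracs`, `flag_degenerate`.
#' @export
enrichment_vs_chance <- function(association, all_genes,
                                 closed_bound_gene_map,
                                 n_perm = 999, seed = 1) {
  stopifnot(inherits(association, "PioneerAssociation"))
  if (n_perm < 100) stop("n_perm must be >= 100")
  assoc_flag <- all_genes %in% names(closed_bound_gene_map)
  degenerate <- all(assoc_flag)
  if (degenerate) {
    return(list(p = 1, observed = association$frac_assoc,
                perm_fracs = rep(1, n_perm), flag_degenerate = TRUE))
  }
  set.seed(seed)
  n_de <- association$n_de
  if (n_de > length(all_genes)) stop("DE set larger than gene universe")
  perm_fracs <- vapply(seq_len(n_perm), function(i) {
    mean(assoc_flag[sample.int(length(all_genes), n_de)])
  }, numeric(1))
  p <- (1 + sum(perm_fracs >= association$frac_assoc)) / (n_perm + 1)
  list(p = p, observed = association$frac_assoc, perm_fracs = perm_fracs,
       flag_degenerate = FALSE)
}
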