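# End-to-end drivers chaining the analysis stages, with machine-readable
# reports. These functions are the programmatic interface; a thin Rscript
# dispatcher over them ships in inst/scripts/pioneerscan.R.

#' Simulate all inputs for a named profile
#'
#' Dispatches on the profile type: `epigenome` profiles produce a genome,
#' coordinated ChIP/ATAC peak sets, occupancy counts and peak sequences;
#' `integration` profiles additionally produce the planted expression table
#' coordinated with closed-chromatin peak placement; `cohort` profiles
#' produce a patient table. With `outdir` the inputs, truth tables and the
#' effective configuration are also written to disk in standard formats.
#'
#' @param profile profile name, YAML path, or [simulation_profile()] object.
#' @param outdir optional output directory (created if needed).
#' @param seed RNG seed; defaults to the profile's seed. Stage seeds are
#'   derived deterministically from it.
#' @param overrides forwarded to [simulation_profile()] when `profile` is a
#'   name.
#' @param sequences generate peak sequences for epigenome profiles (skipped
#'   when the profile has no motif block).
#' @return list of simulated objects (contents depend on the profile type),
#'   with the effective profile under `$profile`.
#' @export
cmd_simulate <- function(profile, outdir = NULL, seed = NULL,
                         overrides = list(), sequences = TRUE) {
  if (!inherits(profile, "SimulationProfile")) {
    profile <- simulation_profile(profile, overrides)
  }
  if (is.null(seed)) seed <- profile$seed
  seed <- as.integer(seed)
  out <- list(profile = profile, seed = seed)
  if (profile$type == "cohort") {
    out$cohort <- generate_cohort(profile, seed = seed)
  } else {
    annotation <- generate_genome(profile, seed = seed)
    out$annotation <- annotation
    plan <- NULL
    if (profile$type == "integration") {
      plan <- plan_integration(profile, annotation, seed = seed + 1L)
      expr <- generate_expression(profile, annotation, seed = seed + 2L,
                                  plan = plan)
      out$expr <- expr$expr
      out$expr_truth <- expr$truth
      out$plan <- plan
    }
    ps <- generate_peaksets(profile, annotation, seed = seed + 3L,
                            assoc_plan = plan$assoc_plan)
    out$peaksets <- ps
    if (sequences && !is.null(profile$motifs)) {
      st <- ps$truth$state[match(ps$chip_ref$peaks$id, ps$truth$peak_id)]
      out$sequences <- generate_peak_sequences(
        profile, ps$chip_ref$peaks, st, seed = seed + 4L)
    }
  }
  if (!is.null(outdir)) write_simulation(out, outdir)
  invisible(out)
}

write_simulation <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  p <- function(f) file.path(outdir, f)
  cfg <- unclass(sim$profile)
  cfg$effective_seed <- sim$seed
  cfg$package_version <- as.character(utils::packageVersion("pioneerscan"))
  yaml::write_yaml(cfg, p("config.yaml"))
  if (!is.null(sim$cohort)) {
    write_cohort(sim$cohort$cohort, p("cohort.tsv"))
    return(invisible(outdir))
  }
  write_gene_annotation(sim$annotation, p("genes.gtf"))
  ps <- sim$peaksets
  write_peaks(ps$chip_ref, p("chip_WT.narrowPeak"), "narrowPeak")
  write_peaks(ps$atac, p("atac_WT.narrowPeak"), "narrowPeak")
  if (!is.null(ps$chip_other)) {
    write_peaks(ps$chip_other,
                p(sprintf("chip_%s.narrowPeak", ps$chip_other$genotype)),
                "narrowPeak")
  }
  utils::write.table(ps$truth, p("peak_truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(ps$counts)) {
    cm <- data.frame(peak_id = rownames(ps$counts$counts), ps$counts$counts,
                     check.names = FALSE)
    utils::write.table(cm, p("peak_counts.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(sim$sequences)) {
    write_sequences(sim$sequences$sequences, p("chip_WT_peaks.fasta"))
  }
  if (!is.null(sim$expr)) {
    em <- data.frame(gene_id = rownames(sim$expr$counts), sim$expr$counts,
                     check.names = FALSE)
    utils::write.table(em, p("expression_counts.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(sim$expr_truth, p("expression_truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(outdir)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(stage, " stage: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full pioneer-factor integration analysis
#'
#' Chains: open/closed classification of the reference ChIP peaks against
#' accessibility -> genomic-location distribution -> (optional) motif
#' enrichment per chromatin class -> (optional) differential occupancy and
#' accessibility of LOST/GAINED peaks -> (optional) differential expression,
#' closed-peak-to-gene association, pioneer association statistics and a
#' permutation enrichment p-value.
#'
#' @param sim a [cmd_simulate()] result, or a list with the same elements
#'   built from files (`peaksets$chip_ref`, `peaksets$atac`, `annotation`,
#'   optionally `peaksets$counts`, `peaksets$chip_other`,
#'   `peaksets$union_peaks`, `expr`, `sequences`).
#' @param min_overlap bp overlap defining "open".
#' @param max_distance peak-to-gene association window (bp).
#' @param fc_min,alpha differential-occupancy thresholds.
#' @param alpha_de,lfc_min differential-expression thresholds.
#' @param cond_a,cond_b expression conditions (earlier, later); default from
#'   the profile.
#' @param n_perm permutations for the enrichment test (0 to skip).
#' @param motif_library motif library for class-wise enrichment.
#' @param n_bg_per_fg shuffled background sequences per foreground sequence.
#' @param threshold_frac motif scan threshold fraction.
#' @param seed seed for permutation and background sampling.
#' @param outdir optional directory for the JSON report and TSV/BED sidecars.
#' @return report list (class `pioneer_report`).
#' @export
cmd_pioneer <- function(sim, min_overlap = 1L, max_distance = 5e4,
                        fc_min = 2, alpha = 1e-4,
                        alpha_de = 0.05, lfc_min = 1,
                        cond_a = NULL, cond_b = NULL,
                        n_perm = 999, motif_library = NULL,
                        n_bg_per_fg = 10L, threshold_frac = 0.8,
                        seed = 1L, outdir = NULL) {
  ps <- sim$peaksets
  if (is.null(ps$chip_ref)) stop("classification stage: missing ChIP peak set")
  if (is.null(ps$atac)) stop("classification stage: missing ATAC peak set")
  params <- list(min_overlap = min_overlap, max_distance = max_distance,
                 fc_min = fc_min, alpha = alpha, alpha_de = alpha_de,
                 lfc_min = lfc_min, n_perm = n_perm,
                 threshold_frac = threshold_frac,
                 n_bg_per_fg = n_bg_per_fg, seed = seed,
                 package_version =
                   as.character(utils::packageVersion("pioneerscan")))
  report <- list(params = params)

  cls <- run_stage("classification",
                   classify_open_closed(ps$chip_ref, ps$atac, min_overlap))
  report$classification <- list(
    n_total = cls$n_total, n_open = cls$n_open, n_closed = cls$n_closed,
    frac_open = cls$frac_open, frac_closed = cls$frac_closed)

  if (!is.null(sim$annotation)) {
    loc <- run_stage("location",
                     location_distribution(cls, ps$chip_ref, sim$annotation))
    report$location <- loc
  }

  if (!is.null(sim$sequences)) {
    if (is.null(motif_library)) motif_library <- default_motif_library()
    seqs <- sim$sequences$sequences
    state <- cls$per_peak$state[match(seqs$names, cls$per_peak$peak_id)]
    report$motifs <- run_stage("motif", {
      lapply(stats::setNames(c("OPEN", "CLOSED"), c("open", "closed")),
             function(st) {
        fg <- seqset_subset(seqs, state == st)
        bg <- sample_background(fg, "dinucleotide-shuffle",
                                n_bg_per_fg = n_bg_per_fg, seed = seed)
        rank_motifs(fg, motif_library, bg, threshold_frac)
      })
    })
  }

  if (!is.null(ps$counts) && !is.null(ps$chip_other)) {
    ref_label <- ps$chip_ref$genotype
    oth_label <- ps$chip_other$genotype
    dp <- run_stage("differential-occupancy",
                    call_differential_peaks(ps$counts, ref_label, oth_label,
                                            fc_min = fc_min, alpha = alpha))
    cmp <- run_stage("comparison",
                     compare_genotype_peaksets(ps$chip_ref, ps$chip_other, dp))
    acc <- run_stage("differential-accessibility",
                     accessibility_of_differential_peaks(
                       cmp, ps$union_peaks, ps$atac, min_overlap))
    report$differential_occupancy <- c(
      attr(dp, "summary"),
      list(n_lost = cmp$n_lost, lost_frac = cmp$lost_frac,
           n_gained = cmp$n_gained, gained_frac = cmp$gained_frac,
           frac_open_lost = acc$frac_open_lost,
           frac_open_gained = acc$frac_open_gained))
    report$diff_peaks <- dp
    report$comparison <- cmp
  }

  if (!is.null(sim$expr)) {
    if (is.null(cond_a)) {
      cond_a <- if (!is.null(sim$profile$expression$cond_a))
        sim$profile$expression$cond_a else "day4"
    }
    if (is.null(cond_b)) {
      cond_b <- if (!is.null(sim$profile$expression$cond_b))
        sim$profile$expression$cond_b else "day5"
    }
    de <- run_stage("differential-expression",
                    differential_expression(sim$expr, cond_a, cond_b,
                                            alpha_de = alpha_de,
                                            lfc_min = lfc_min))
    closed_ids <- cls$per_peak$peak_id[cls$per_peak$state == "CLOSED"]
    closed_peaks <- ps$chip_ref$peaks[ps$chip_ref$peaks$id %in% closed_ids, ]
    assoc <- run_stage("association",
                       associate_peaks_to_genes(closed_peaks, sim$annotation,
                                                max_distance = max_distance))
    pa <- run_stage("pioneer-association",
                    pioneer_association_stats(de, assoc$gene_map))
    report$expression <- list(
      n_genes = nrow(sim$expr$counts),
      n_de = sum(de$call != "NS"),
      n_up = sum(de$call == "UP"), n_down = sum(de$call == "DOWN"))
    report$pioneer <- list(
      n_de = pa$n_de, n_assoc = pa$n_assoc, frac_assoc = pa$frac_assoc,
      n_up = pa$n_up, frac_up = pa$frac_up,
      n_closed_peaks = length(closed_ids),
      n_peaks_assigned = assoc$n_assigned,
      n_peaks_unassigned = assoc$n_unassigned)
    if (n_perm > 0) {
      enr <- run_stage("enrichment-vs-chance",
                       enrichment_vs_chance(pa, rownames(sim$expr$counts),
                                            assoc$gene_map,
                                            n_perm = n_perm, seed = seed))
      report$pioneer$perm_p <- enr$p
    }
    report$de_results <- de
    report$association <- pa
  }

  class(report) <- "pioneer_report"
  if (!is.null(outdir)) write_pioneer_report(report, outdir)
  report
}

write_pioneer_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  keep <- setdiff(names(report),
                  c("diff_peaks", "de_results", "comparison", "association"))
  jsonlite::write_json(report[keep], file.path(outdir, "pioneer_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  if (!is.null(report$diff_peaks)) {
    utils::write.table(report$diff_peaks,
                       file.path(outdir, "differential_peaks.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(report$de_results)) {
    utils::write.table(report$de_results,
                       file.path(outdir, "differential_expression.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(report$association)) {
    utils::write.table(report$association$evidence,
                       file.path(outdir, "pioneer_evidence.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(outdir)
}

#' @export
print.pioneer_report <- function(x, ...) {
  cat("pioneer_report\n")
  cat(sprintf("  classification: %d peaks, %.1f%% open\n",
              x$classification$n_total, 100 * x$classification$frac_open))
  if (!is.null(x$differential_occupancy)) {
    d <- x$differential_occupancy
    cat(sprintf("  occupancy: %d REDUCED (%.1f%% of reference), %d INCREASED (%.1f%% of other)\n",
                d$n_lost, 100 * d$lost_frac, d$n_gained, 100 * d$gained_frac))
    if (!is.na(d$frac_open_lost)) {
      cat(sprintf("  accessibility of LOST peaks: %.1f%% open\n",
                  100 * d$frac_open_lost))
    }
  }
  if (!is.null(x$pioneer)) {
    cat(sprintf("  integration: %d DE genes, %.1f%% associated with closed binding, %.1f%% of those UP\n",
                x$pioneer$n_de, 100 * x$pioneer$frac_assoc,
                100 * x$pioneer$frac_up))
  }
  invisible(x)
}

#' Run the cohort statistics analysis
#'
#' Produces the flag summary (counts and percentages overall and per variant
#' class), the pre-specified-window binomial clustering test over missense
#' residue positions, and the genotype-phenotype Fisher tests
#' (extracardiac x variant class; pancreatic agenesis / diaphragmatic hernia
#' x exon-4 missense).
#'
#' @param cohort a `CohortTable`, a path to a cohort TSV, or a
#'   [cmd_simulate()] cohort result.
#' @param window residue window for the clustering test and the exon-4
#'   stratification.
#' @param protein_length protein length (amino acids).
#' @param outdir optional directory for the JSON report.
#' @return report list (class `cohort_report`).
#' @export
cmd_cohort <- function(cohort, window = c(435L, 477L),
                       protein_length = 595L, outdir = NULL) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  if (!inherits(cohort, "CohortTable") && !is.null(cohort$cohort)) {
    cohort <- cohort$cohort
  }
  stopifnot(inherits(cohort, "CohortTable"))
  summary_tab <- cohort_summary(cohort)
  mis <- cohort$variant_class == "missense" & !is.na(cohort$residue_position)
  n <- sum(mis)
  k <- sum(mis & cohort$residue_position >= window[1] &
             cohort$residue_position <= window[2])
  n_excluded <- sum(cohort$variant_class == "missense" &
                      is.na(cohort$residue_position))
  clustering <- list(
    k = k, n = n, window = window, protein_length = protein_length,
    n_excluded_no_position = n_excluded,
    p = binomial_window_test(k, n, diff(window) + 1L, protein_length))
  assoc_ec <- phenotype_association(cohort, "extracardiac", "variant_class")
  assoc_pa <- phenotype_association(cohort, "pa_cdh", "exon4_missense",
                                    window = window)
  report <- list(
    params = list(window = window, protein_length = protein_length,
                  package_version =
                    as.character(utils::packageVersion("pioneerscan"))),
    n_patients = nrow(cohort),
    summary = summary_tab,
    clustering = clustering,
    extracardiac_by_class = list(
      table = assoc_ec$table,
      p_two_sided = assoc_ec$fisher$p_two_sided,
      odds_ratio = assoc_ec$fisher$odds_ratio),
    pa_cdh_by_exon4 = list(
      table = assoc_pa$table,
      p_one_sided = assoc_pa$fisher$p_one_sided,
      p_two_sided = assoc_pa$fisher$p_two_sided,
      odds_ratio = assoc_pa$fisher$odds_ratio))
  class(report) <- "cohort_report"
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(unclass(report),
                         file.path(outdir, "cohort_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows", matrix = "rowmajor")
  }
  report
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("cohort_report: %d patients\n", x$n_patients))
  ov <- x$summary[x$summary$stratum == "overall", ]
  for (i in seq_len(nrow(ov))) {
    cat(sprintf("  %s: %d/%d (%.1f%%)\n", ov$flag[i], ov$n[i],
                ov$total[i], ov$percent[i]))
  }
  cat(sprintf("  clustering: %d/%d missense in window %d-%d, p = %.3g\n",
              x$clustering$k, x$clustering$n, x$clustering$window[1],
              x$clustering$window[2], x$clustering$p))
  cat(sprintf("  pa_cdh x exon-4 missense: one-sided p = %.3g, OR = %.3g\n",
              x$pa_cdh_by_exon4$p_one_sided, x$pa_cdh_by_exon4$odds_ratio))
  invisible(x)
}
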