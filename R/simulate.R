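# Seeded synthetic-data generators with planted ground truth. Named profiles
# shipped under inst/extdata/profiles mirror the headline study conditions:
# peak totals, open-chromatin fraction, reduced/increased occupancy fractions,
# DE-set size and the closed-binding/activation association fractions.
# Membership fractions (open/closed, reduced, DE, associated) are planted
# exactly by construction; read counts are the only stochastic layer.

#' Load a simulation profile
#'
#' Profiles are YAML files shipped with the package (`wt_day4`, `r456g_day4`,
#' `het_day4`, `wt_expression`, `cohort_paper`) or user paths. Overrides are
#' merged recursively, e.g. `list(peaks = list(n_chip = 500))` for a scaled-
#' down test run.
#'
#' @param name profile name or path to a YAML file.
#' @param overrides named list merged over the file contents.
#' @return An object of class `SimulationProfile`.
#' @export
simulation_profile <- function(name, overrides = list()) {
  path <- if (file.exists(name)) name else
    system.file("extdata", "profiles", paste0(name, ".yaml"),
                package = "pioneerscan")
  if (!nzchar(path) || !file.exists(path)) {
    stop("unknown simulation profile: ", name)
  }
  prof <- yaml::read_yaml(path)
  prof <- modify_list_deep(prof, overrides)
  structure(prof, class = "SimulationProfile")
}

modify_list_deep <- function(base, new) {
  for (nm in names(new)) {
    if (is.list(new[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- modify_list_deep(base[[nm]], new[[nm]])
    } else {
      base[[nm]] <- new[[nm]]
    }
  }
  base
}

#' @export
print.SimulationProfile <- function(x, ...) {
  cat(sprintf("SimulationProfile '%s' (type %s, seed %s)\n",
              x$name, x$type, x$seed))
  invisible(x)
}

# triangular-distribution sample, rounded to integer lengths
rtri <- function(n, min, mode, max) {
  u <- stats::runif(n)
  fc <- (mode - min) / (max - min)
  out <- ifelse(u < fc,
                min + sqrt(u * (max - min) * (mode - min)),
                max - sqrt((1 - u) * (max - min) * (max - mode)))
  as.integer(round(out))
}

#' Generate a synthetic genome annotation
#'
#' Places non-overlapping genes with a minimum TSS spacing uniformly along
#' each chromosome (random strand, triangular gene-length distribution, 2-5
#' exons per gene). With `with_sequence = TRUE` (desk-scale genomes only,
#' <= 50 Mb) an i.i.d. background sequence at the configured GC content is
#' returned alongside.
#'
#' @param profile a [simulation_profile()].
#' @param seed RNG seed (defaults to the profile seed).
#' @param with_sequence also generate chromosome sequences.
#' @return A [genome_annotation()]; with sequence, a list
#'   `(annotation, sequence)`.
#' @export
generate_genome <- function(profile, seed = profile$seed,
                            with_sequence = FALSE) {
  g <- profile$genome
  set.seed(seed)
  chroms <- sprintf("chr%d", seq_len(g$n_chrom))
  chrom_sizes <- stats::setNames(rep(g$chrom_length, g$n_chrom), chroms)
  per <- diff(round(seq(0, g$n_genes, length.out = g$n_chrom + 1)))
  margin <- g$margin
  genes <- vector("list", g$n_chrom)
  exons <- vector("list", g$n_chrom)
  gid0 <- 0L
  for (ci in seq_len(g$n_chrom)) {
    k <- per[ci]
    if (k == 0) next
    span <- g$chrom_length - 2 * margin
    slack <- span - (k - 1) * g$min_tss_spacing
    if (slack <= 0) stop("genes cannot fit at the required spacing")
    tss <- margin + sort(stats::runif(k, 0, slack)) +
      (seq_len(k) - 1) * g$min_tss_spacing
    tss <- round(tss)
    strand <- sample(c("+", "-"), k, replace = TRUE)
    len <- rtri(k, g$gene_length_min,
                (g$gene_length_min + g$gene_length_max) / 2,
                g$gene_length_max)
    start <- ifelse(strand == "+", tss, tss + 1 - len)
    end <- start + len
    ids <- sprintf("gene_%05d", gid0 + seq_len(k))
    gid0 <- gid0 + k
    genes[[ci]] <- data.frame(gene_id = ids, chrom = chroms[ci],
                              start = start, end = end, strand = strand,
                              stringsAsFactors = FALSE)
    # 2-5 exons per gene: sorted internal cut points, alternating exon/intron
    nex <- sample(2:5, k, replace = TRUE)
    ex <- lapply(seq_len(k), function(i) {
      cuts <- sort(sample.int(len[i] - 1, 2 * nex[i] - 2))
      bounds <- c(0, cuts, len[i])
      es <- bounds[seq(1, length(bounds) - 1, by = 2)]
      ee <- bounds[seq(2, length(bounds), by = 2)]
      data.frame(gene_id = ids[i], chrom = chroms[ci],
                 start = start[i] + es, end = start[i] + ee,
                 stringsAsFactors = FALSE)
    })
    exons[[ci]] <- do.call(rbind, ex)
  }
  ann <- genome_annotation(chrom_sizes, do.call(rbind, genes),
                           do.call(rbind, exons))
  if (!with_sequence) return(ann)
  if (sum(chrom_sizes) > 5e7) {
    stop("with_sequence requires a desk-scale genome (<= 50 Mb total)")
  }
  gc <- if (!is.null(profile$motifs$gc)) profile$motifs$gc else 0.41
  seqs <- vapply(chrom_sizes, function(L) {
    codes_to_string(sample.int(4L, L, replace = TRUE,
                               prob = c((1 - gc) / 2, gc / 2,
                                        gc / 2, (1 - gc) / 2)))
  }, character(1))
  list(annotation = ann, sequence = seqs)
}

# Sample n distal slot centers, pairwise >= ~2 kb apart and outside every
# TSS exclusion zone, by drawing distinct bins from the allowed gaps.
sample_distal_slots <- function(annotation, n, excl, bin = 2500L,
                                jitter = 500L, margin = 1e5) {
  gaps <- list()
  for (ch in names(annotation$chrom_sizes)) {
    L <- annotation$chrom_sizes[[ch]]
    tss <- sort(annotation$genes$tss[annotation$genes$chrom == ch])
    lo <- c(margin, tss + excl)
    hi <- c(tss - excl, L - margin)
    keep <- hi - lo >= bin + jitter
    if (any(keep)) {
      gaps[[ch]] <- data.frame(chrom = ch, lo = lo[keep], hi = hi[keep])
    }
  }
  gaps <- do.call(rbind, gaps)
  nbins <- floor((gaps$hi - gaps$lo - jitter) / bin)
  total <- sum(nbins)
  if (n > total) stop("insufficient genome space for distal placements")
  cum <- cumsum(nbins)
  pick <- sort(sample.int(total, n))
  gi <- findInterval(pick, c(0, cum), left.open = TRUE)  # gap index, 1-based
  within <- pick - c(0, cum)[gi] - 1L
  center <- gaps$lo[gi] + within * bin + floor(stats::runif(n, 0, jitter))
  data.frame(chrom = gaps$chrom[gi], center = center,
             stringsAsFactors = FALSE)
}

#' Generate coordinated ChIP and ATAC peak sets with planted truth
#'
#' Plants exactly `round(frac_open * n_chip)` ChIP peaks inside ATAC peaks
#' (a configured fraction of them at promoters) and the rest clear of all
#' accessibility peaks; optionally plants genotype-specific REDUCED /
#' INCREASED occupancy categories and gene-proximal closed peaks for an
#' association plan. Read counts are drawn per genotype at the configured
#' depth and fold (Poisson, or negative binomial when `dispersion > 0`) with
#' matched library sizes.
#'
#' @param profile a [simulation_profile()] with `peaks` / `occupancy` (and
#'   optionally `genotype`) blocks.
#' @param annotation a [generate_genome()] result.
#' @param seed RNG seed.
#' @param assoc_plan optional data.frame (`gene_id`, `kind`) of genes that
#'   must receive one closed ChIP peak within the association window.
#' @return list with `chip_ref`, `chip_other` (or NULL), `atac`
#'   ([peak_set()]s), `counts` ([count_table()] over the union peak set, or
#'   NULL), `union_peaks` (interval data.frame) and `truth` (per-peak planted
#'   state/call/association).
#' @export
generate_peaksets <- function(profile, annotation, seed = profile$seed,
                              assoc_plan = NULL) {
  pk <- profile$peaks
  occ <- profile$occupancy
  gt <- profile$genotype
  set.seed(seed)

  day <- if (is.null(profile$day)) NA_integer_ else as.integer(profile$day)
  n_chip <- pk$n_chip
  n_open <- round(pk$frac_open * n_chip)
  n_closed <- n_chip - n_open
  if (is.null(pk$frac_open_promoter)) pk$frac_open_promoter <- 0
  n_op <- round(pk$frac_open_promoter * n_open)   # promoter-proximal open
  n_od <- n_open - n_op                           # distal open
  n_assoc <- if (is.null(assoc_plan)) 0L else nrow(assoc_plan)
  if (n_assoc > n_closed) stop("association plan exceeds closed peak count")
  n_cd <- n_closed - n_assoc                      # distal closed

  n_reduced <- if (is.null(gt)) 0L else round(gt$frac_reduced * n_chip)
  n_increased <- if (is.null(gt)) 0L else round(gt$frac_increased * gt$n_other)
  n_shared <- if (is.null(gt)) 0L else
    min(n_chip - n_reduced, gt$n_other - n_increased)
  n_oo_unch <- if (is.null(gt)) 0L else gt$n_other - n_increased - n_shared

  # --- placement -----------------------------------------------------------
  n_distal <- n_od + n_cd + (pk$n_atac - n_open) + n_increased + n_oo_unch
  slots <- sample_distal_slots(annotation, n_distal, pk$tss_exclusion,
                               bin = pk$slot_bin, jitter = pk$slot_jitter,
                               margin = profile$genome$margin)
  take <- function(n) {
    if (n == 0) return(slots[0, , drop = FALSE])
    out <- slots[seq_len(n), , drop = FALSE]
    slots <<- slots[-seq_len(n), , drop = FALSE]
    out
  }
  genes <- annotation$genes
  # promoter-proximal open peaks: midpoint inside the promoter window
  prom_pool <- setdiff(genes$gene_id,
                       if (is.null(assoc_plan)) character(0)
                       else assoc_plan$gene_id)
  prom_genes <- sample(prom_pool, n_op)
  pg <- genes[match(prom_genes, genes$gene_id), ]
  prom_centers <- data.frame(
    chrom = pg$chrom,
    center = pg$tss + ifelse(pg$strand == "+", 1L, -1L) *
      sample(-1000:100, n_op, replace = TRUE))
  # association peaks: one closed peak 5-40 kb from the planned gene's TSS
  if (n_assoc > 0) {
    ag <- genes[match(assoc_plan$gene_id, genes$gene_id), ]
    offs <- round(stats::runif(n_assoc, pk$assoc_dist_min, pk$assoc_dist_max)) *
      sample(c(-1L, 1L), n_assoc, replace = TRUE)
    assoc_centers <- data.frame(chrom = ag$chrom, center = ag$tss + offs)
  }

  lens_chip <- rtri(n_chip, pk$chip_len_min, pk$chip_len_mode, pk$chip_len_max)

  chip <- data.frame(
    chrom = character(n_chip), center = numeric(n_chip),
    state = character(n_chip), placement = character(n_chip),
    assoc_gene = NA_character_, stringsAsFactors = FALSE)
  i <- 0
  fill <- function(df, n, centers, state, placement, assoc = NA_character_) {
    idx <- i + seq_len(n)
    df$chrom[idx] <- centers$chrom
    df$center[idx] <- centers$center
    df$state[idx] <- state
    df$placement[idx] <- placement
    df$assoc_gene[idx] <- assoc
    i <<- i + n
    df
  }
  chip <- fill(chip, n_op, prom_centers, "OPEN", "promoter")
  chip <- fill(chip, n_od, take(n_od), "OPEN", "distal")
  if (n_assoc > 0) {
    chip <- fill(chip, n_assoc, assoc_centers, "CLOSED", "tss_proximal",
                 assoc_plan$gene_id)
  }
  chip <- fill(chip, n_cd, take(n_cd), "CLOSED", "distal")
  chip$start <- chip$center - floor(lens_chip / 2)
  chip$end <- chip$start + lens_chip
  chip$id <- sprintf("chip_%05d", seq_len(n_chip))

  # planted differential call for reference-set peaks
  chip$call <- "UNCHANGED"
  if (n_reduced > 0) {
    open_idx <- which(chip$state == "OPEN")
    closed_idx <- which(chip$state == "CLOSED" & chip$placement == "distal")
    n_open_red <- if (!is.null(gt$frac_open_reduced)) {
      round(gt$frac_open_reduced * n_reduced)
    } else {
      round(pk$frac_open * n_reduced)
    }
    chip$call[sample(open_idx, n_open_red)] <- "REDUCED"
    chip$call[sample(closed_idx, n_reduced - n_open_red)] <- "REDUCED"
  }

  # ATAC: one peak containing each open ChIP peak, plus standalone peaks
  open_sel <- chip$state == "OPEN"
  extra <- round(stats::runif(n_open, pk$atac_extra_min, pk$atac_extra_max))
  u <- floor(stats::runif(n_open, 0, extra + 1))
  atac_paired <- data.frame(chrom = chip$chrom[open_sel],
                            start = chip$start[open_sel] - u,
                            end = chip$end[open_sel] + (extra - u))
  n_as <- pk$n_atac - n_open
  asl <- take(n_as)
  lens_atac <- rtri(n_as, pk$chip_len_min, pk$chip_len_mode,
                    pk$chip_len_max) +
    round(stats::runif(n_as, pk$atac_extra_min, pk$atac_extra_max))
  atac <- rbind(atac_paired,
                data.frame(chrom = asl$chrom,
                           start = asl$center - floor(lens_atac / 2),
                           end = asl$center - floor(lens_atac / 2) + lens_atac))
  atac$id <- sprintf("atac_%05d", seq_len(nrow(atac)))

  # other-genotype-only peaks (ectopic)
  other_only <- NULL
  if (!is.null(gt)) {
    n_oo <- n_increased + n_oo_unch
    ool <- take(n_oo)
    lens_oo <- rtri(n_oo, pk$chip_len_min, pk$chip_len_mode, pk$chip_len_max)
    other_only <- data.frame(
      chrom = ool$chrom, start = ool$center - floor(lens_oo / 2),
      end = ool$center - floor(lens_oo / 2) + lens_oo,
      id = sprintf("mchip_%05d", seq_len(n_oo)),
      state = "CLOSED", placement = "distal", assoc_gene = NA_character_,
      call = rep(c("INCREASED", "UNCHANGED"), c(n_increased, n_oo_unch)),
      stringsAsFactors = FALSE)
  }

  # membership of reference peaks in the other genotype's called set
  in_other <- rep(FALSE, n_chip)
  if (!is.null(gt)) {
    unch_idx <- which(chip$call == "UNCHANGED")
    in_other[sample(unch_idx, n_shared)] <- TRUE
  }

  # --- counts --------------------------------------------------------------
  counts <- NULL
  draw <- function(mu) {
    if (is.null(occ$dispersion) || occ$dispersion == 0) {
      stats::rpois(length(mu), mu)
    } else {
      stats::rnbinom(length(mu), mu = mu, size = 1 / occ$dispersion)
    }
  }
  d <- occ$depth
  f <- occ$fold
  if (!is.null(gt)) {
    rate_ref <- c(ifelse(chip$call == "REDUCED", d, d),
                  ifelse(other_only$call == "INCREASED", d / f, d / f))
    rate_oth <- c(ifelse(chip$call == "REDUCED", d / f, d),
                  ifelse(other_only$call == "INCREASED", d, d / f))
    ids <- c(chip$id, other_only$id)
    cm <- cbind(draw(rate_ref), draw(rate_oth))
    rownames(cm) <- ids
    colnames(cm) <- c("WT", gt$label)
    counts <- count_table(cm, condition = c("WT", gt$label),
                          lib_sizes = rep(occ$lib_size, 2))
  } else {
    cm <- matrix(draw(rep(d, n_chip)), ncol = 1,
                 dimnames = list(chip$id, "WT"))
  }

  # --- assemble ------------------------------------------------------------
  chip_cols <- c("id", "chrom", "start", "end")
  chip_ref <- peak_set(chip[, chip_cols], name = "chip_WT", assay = "CHIP",
                       genotype = "WT", day = day,
                       counts = if (is.null(gt)) cm else NULL,
                       annotation = annotation)
  atac_ps <- peak_set(atac[, c("id", "chrom", "start", "end")],
                      name = "atac_WT", assay = "ATAC", genotype = "WT",
                      day = day, annotation = annotation)
  chip_other <- NULL
  union_peaks <- chip[, chip_cols]
  if (!is.null(gt)) {
    other_df <- rbind(chip[in_other, chip_cols], other_only[, chip_cols])
    chip_other <- peak_set(other_df, name = paste0("chip_", gt$label),
                           assay = "CHIP", genotype = gt$label,
                           day = day, annotation = annotation)
    union_peaks <- rbind(union_peaks, other_only[, chip_cols])
  }
  truth_cols <- c("id", "chrom", "start", "end", "state", "placement",
                  "assoc_gene", "call")
  truth <- chip[, truth_cols]
  truth$in_reference <- TRUE
  truth$in_other <- in_other
  if (!is.null(other_only)) {
    oo <- other_only[, truth_cols]
    oo$in_reference <- FALSE
    oo$in_other <- TRUE
    truth <- rbind(truth, oo)
  }
  names(truth)[1] <- "peak_id"
  list(chip_ref = chip_ref, chip_other = chip_other, atac = atac_ps,
       counts = counts, union_peaks = union_peaks, truth = truth)
}

#' Generate peak sequences with planted class-specific motif instances
#'
#' Each peak gets an i.i.d. background sequence at the configured GC content;
#' with the class-specific planting probability a single motif instance
#' (sampled from the PWM, random offset and strand) is written into it.
#'
#' @param profile a [simulation_profile()] with a `motifs` block.
#' @param peaks interval data.frame (`id`, `start`, `end`) for the sequences.
#' @param states per-peak chromatin class (`"OPEN"` / `"CLOSED"`), parallel
#'   to `peaks`.
#' @param seed RNG seed.
#' @param library motif library (defaults to the bundled one).
#' @return list with `sequences` (a `seq_set` named by peak id) and `truth`
#'   (data.frame `peak_id`, `planted`, `motif`, `offset`, `strand`).
#' @export
generate_peak_sequences <- function(profile, peaks, states,
                                    seed = profile$seed,
                                    library = default_motif_library()) {
  mo <- profile$motifs
  set.seed(seed)
  lens <- as.integer(peaks$end - peaks$start)
  n <- length(lens)
  stopifnot(length(states) == n)
  gc <- mo$gc
  codes <- sample.int(4L, sum(lens), replace = TRUE,
                      prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  ends <- cumsum(lens)
  starts0 <- c(0L, ends[-n])
  cfg <- list(OPEN = list(motif = mo$open_motif, rate = mo$open_rate),
              CLOSED = list(motif = mo$closed_motif, rate = mo$closed_rate))
  truth <- data.frame(peak_id = peaks$id, planted = FALSE,
                      motif = NA_character_, offset = NA_integer_,
                      strand = NA_character_, stringsAsFactors = FALSE)
  for (cls in names(cfg)) {
    pwm <- library[[cfg[[cls]]$motif]]
    if (is.null(pwm)) stop("motif not in library: ", cfg[[cls]]$motif)
    w <- pwm_width(pwm)
    lo <- log2(pwm$mat / pwm$background)
    thr <- 0.8 * pwm_max_score(pwm)  # planted sites score as sites
    idx <- which(states == cls & lens >= w)
    if (any(states == cls & lens < w)) {
      stop("motif ", pwm$name, " longer than some ", cls, " peaks")
    }
    planted <- idx[stats::runif(length(idx)) < cfg[[cls]]$rate]
    if (length(planted) == 0) next
    offs <- floor(stats::runif(length(planted)) * (lens[planted] - w + 1))
    strands <- sample(c("+", "-"), length(planted), replace = TRUE)
    for (j in seq_along(planted)) {
      for (try in 1:50) {
        inst <- vapply(seq_len(w), function(col) {
          sample.int(4L, 1L, prob = pwm$mat[, col])
        }, integer(1))
        if (sum(lo[cbind(inst, seq_len(w))]) >= thr) break
        if (try == 50) inst <- apply(pwm$mat, 2, which.max)
      }
      if (strands[j] == "-") inst <- rev(5L - inst)
      pos <- starts0[planted[j]] + offs[j] + seq_len(w)
      codes[pos] <- inst
    }
    truth$planted[planted] <- TRUE
    truth$motif[planted] <- cfg[[cls]]$motif
    truth$offset[planted] <- offs
    truth$strand[planted] <- strands
  }
  list(sequences = new_seqset(codes, lens, peaks$id), truth = truth)
}

#' Simulate one chromatin class's peak sequences (ranking experiments)
#'
#' Convenience wrapper around [generate_peak_sequences()] that draws peak
#' lengths from the profile and plants the profile's class motifs, without
#' requiring genomic placement. Used to replicate motif-ranking runs across
#' seeds.
#'
#' @param profile a [simulation_profile()].
#' @param seed RNG seed.
#' @param n_open,n_closed class sizes; default to the profile's planted
#'   open/closed split.
#' @return as [generate_peak_sequences()], plus `states`.
#' @export
simulate_class_sequences <- function(profile, seed,
                                     n_open = NULL, n_closed = NULL) {
  pk <- profile$peaks
  if (is.null(n_open)) n_open <- round(pk$frac_open * pk$n_chip)
  if (is.null(n_closed)) n_closed <- pk$n_chip - n_open
  set.seed(seed)
  n <- n_open + n_closed
  lens <- rtri(n, pk$chip_len_min, pk$chip_len_mode, pk$chip_len_max)
  peaks <- data.frame(id = sprintf("peak_%05d", seq_len(n)),
                      start = 0L, end = lens)
  states <- rep(c("OPEN", "CLOSED"), c(n_open, n_closed))
  out <- generate_peak_sequences(profile, peaks, states, seed = seed + 1L)
  out$states <- states
  out
}

#' Plan the expression / closed-binding integration
#'
#' Chooses the planted DE gene set, the exact subset that must carry a
#' closed-chromatin peak within the association window (`frac_assoc`), the
#' exact fraction of those planted as activated (`frac_up`), directions for
#' the remaining DE genes (balanced), and a background set of non-DE genes
#' with nearby closed binding (`bg_assoc_rate`).
#'
#' @param profile a [simulation_profile()] with an `expression` block.
#' @param annotation a [generate_genome()] result.
#' @param seed RNG seed.
#' @return list with `de_genes`, `direction` (named), `assoc_genes`,
#'   `assoc_up_genes`, `bg_assoc_genes` and the `assoc_plan` data.frame for
#'   [generate_peaksets()].
#' @export
plan_integration <- function(profile, annotation, seed = profile$seed) {
  ex <- profile$expression
  set.seed(seed)
  gene_ids <- annotation$genes$gene_id
  if (ex$n_de > length(gene_ids)) stop("n_de exceeds the number of genes")
  de <- sample(gene_ids, ex$n_de)
  n_assoc <- round(ex$frac_assoc * ex$n_de)
  assoc <- sample(de, n_assoc)
  n_up <- round(ex$frac_up * n_assoc)
  assoc_up <- sample(assoc, n_up)
  direction <- stats::setNames(rep("DOWN", ex$n_de), de)
  direction[assoc] <- "DOWN"
  direction[assoc_up] <- "UP"
  rest <- setdiff(de, assoc)
  direction[sample(rest, round(length(rest) / 2))] <- "UP"
  non_de <- setdiff(gene_ids, de)
  bg <- sample(non_de, round(ex$bg_assoc_rate * length(non_de)))
  assoc_plan <- data.frame(
    gene_id = c(assoc, bg),
    kind = rep(c("de_assoc", "bg_assoc"), c(length(assoc), length(bg))),
    stringsAsFactors = FALSE)
  list(de_genes = de, direction = direction, assoc_genes = assoc,
       assoc_up_genes = assoc_up, bg_assoc_genes = bg,
       assoc_plan = assoc_plan)
}

#' Generate a gene x sample expression count table with planted DE
#'
#' Baselines are log-normal; planted DE genes change by
#' `2^U(lfc_min, lfc_max)` in the planted direction at the later time point.
#' Counts are negative binomial at the configured dispersion, with matched
#' library sizes across samples.
#'
#' @param profile a [simulation_profile()] with an `expression` block.
#' @param annotation a [generate_genome()] result.
#' @param seed RNG seed.
#' @param plan a [plan_integration()] result (created if `NULL`).
#' @return list with `expr` (a [count_table()]), `truth` (per-gene planted
#'   status) and `plan`.
#' @export
generate_expression <- function(profile, annotation, seed = profile$seed,
                                plan = NULL) {
  ex <- profile$expression
  if (is.null(plan)) plan <- plan_integration(profile, annotation, seed)
  set.seed(seed + 1L)
  gene_ids <- annotation$genes$gene_id
  n <- length(gene_ids)
  base <- stats::rlnorm(n, ex$meanlog, ex$sdlog)
  # planted DE genes sit at robustly quantifiable expression: real DE sets
  # are by construction detected genes, so baselines below the floor are
  # redrawn from the truncated upper tail for planted genes
  if (!is.null(ex$de_min_base) && ex$de_min_base > 0) {
    de_idx <- which(gene_ids %in% plan$de_genes & base < ex$de_min_base)
    while (length(de_idx) > 0) {
      base[de_idx] <- stats::rlnorm(length(de_idx), ex$meanlog, ex$sdlog)
      de_idx <- de_idx[base[de_idx] < ex$de_min_base]
    }
  }
  lfc <- stats::setNames(rep(0, n), gene_ids)
  lfc[plan$de_genes] <- stats::runif(length(plan$de_genes),
                                     ex$lfc_min, ex$lfc_max) *
    ifelse(plan$direction[plan$de_genes] == "UP", 1, -1)
  mu_a <- base
  mu_b <- base * 2^lfc
  reps <- ex$replicates
  size <- 1 / ex$dispersion
  draw <- function(mu) stats::rnbinom(length(mu), mu = mu, size = size)
  cols <- list()
  for (r in seq_len(reps)) cols[[r]] <- draw(mu_a)
  for (r in seq_len(reps)) cols[[reps + r]] <- draw(mu_b)
  cm <- do.call(cbind, cols)
  rownames(cm) <- gene_ids
  colnames(cm) <- c(paste0(ex$cond_a, "_", seq_len(reps)),
                    paste0(ex$cond_b, "_", seq_len(reps)))
  condition <- rep(c(ex$cond_a, ex$cond_b), each = reps)
  expr <- count_table(cm, condition, lib_sizes = rep(ex$lib_size, 2 * reps))
  truth <- data.frame(
    gene_id = gene_ids,
    is_de = gene_ids %in% plan$de_genes,
    lfc = as.numeric(lfc),
    direction = ifelse(gene_ids %in% plan$de_genes,
                       plan$direction[gene_ids], NA),
    assoc = gene_ids %in% plan$assoc_genes,
    assoc_up = gene_ids %in% plan$assoc_up_genes,
    bg_assoc = gene_ids %in% plan$bg_assoc_genes,
    stringsAsFactors = FALSE)
  list(expr = expr, truth = truth, plan = plan)
}

#' Generate a synthetic patient cohort
#'
#' In `exact` mode the configured margins are reproduced exactly (variant
#' class sizes, per-stratum flag counts, exon-4 missense count), with residue
#' positions sampled inside/outside the window; patients with pancreatic
#' agenesis / diaphragmatic hernia are included among the extracardiac
#' carriers. In `rates` mode flags are Bernoulli draws at per-stratum rates.
#'
#' @param profile a [simulation_profile()] with a `cohort` block.
#' @param seed RNG seed.
#' @return list with `cohort` (a `CohortTable`) and `config` (the planted
#'   margins).
#' @export
generate_cohort <- function(profile, seed = profile$seed) {
  co <- profile$cohort
  set.seed(seed)
  w <- as.integer(co$window)
  L <- as.integer(co$protein_length)
  n_lof <- co$n_lof
  n_mis <- co$n_missense
  n_e4 <- co$n_exon4_missense
  if (n_e4 > n_mis) stop("exon-4 missense count exceeds missense count")
  window_res <- w[1]:w[2]
  other_res <- setdiff(seq_len(L), window_res)
  pos_mis <- c(sample(window_res, n_e4, replace = TRUE),
               sample(other_res, n_mis - n_e4, replace = TRUE))
  # about a third of LoF variants are splice/frameshift without a clean
  # residue position
  pos_lof <- sample(seq_len(L), n_lof, replace = TRUE)
  pos_lof[stats::runif(n_lof) < 1 / 3] <- NA_integer_
  df <- data.frame(
    patient_id = sprintf("pt_%03d", seq_len(n_lof + n_mis)),
    variant_class = rep(c("LoF", "missense"), c(n_lof, n_mis)),
    residue_position = c(pos_lof, pos_mis),
    extracardiac = FALSE, pa_cdh = FALSE, neuro = FALSE,
    stringsAsFactors = FALSE)
  is_lof <- df$variant_class == "LoF"
  is_e4 <- !is_lof & !is.na(df$residue_position) &
    df$residue_position >= w[1] & df$residue_position <= w[2]
  if (identical(co$mode, "exact")) {
    pick <- function(idx, n) if (n > 0) sample(idx, n) else integer(0)
    # pa_cdh first, then extracardiac as a superset where counts allow
    pa_lof <- pick(which(is_lof), co$pa_cdh$LoF)
    pa_e4 <- pick(which(is_e4), co$pa_cdh$exon4_missense)
    pa_other <- pick(which(!is_lof & !is_e4), co$pa_cdh$other_missense)
    df$pa_cdh[c(pa_lof, pa_e4, pa_other)] <- TRUE
    fill_super <- function(class_idx, pa_idx, n) {
      base <- intersect(class_idx, c(pa_idx))
      base <- utils::head(base, n)
      extra <- pick(setdiff(class_idx, base), n - length(base))
      c(base, extra)
    }
    ec_lof <- fill_super(which(is_lof), pa_lof, co$extracardiac$LoF)
    ec_mis <- fill_super(which(!is_lof), c(pa_e4, pa_other),
                         co$extracardiac$missense)
    df$extracardiac[c(ec_lof, ec_mis)] <- TRUE
    df$neuro[c(pick(which(is_lof), co$neuro$LoF),
               pick(which(!is_lof), co$neuro$missense))] <- TRUE
  } else {
    for (fl in c("extracardiac", "pa_cdh", "neuro")) {
      r <- co$rates[[fl]]
      df[[fl]][is_lof] <- stats::runif(sum(is_lof)) < r$LoF
      df[[fl]][!is_lof] <- stats::runif(sum(!is_lof)) < r$missense
    }
  }
  list(cohort = as_cohort_table(df, protein_length = L), config = co)
}
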