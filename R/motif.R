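# Position weight matrices, log-odds scanning on both strands, background
# construction and class-wise motif enrichment.

#' Build a position weight matrix from aligned binding sites
#'
#' Column probabilities are `(count + pseudocount) / (n + 4 * pseudocount)`.
#'
#' @param sites character vector of equal-length ACGT sequences.
#' @param pseudocount non-negative pseudocount per base.
#' @param background base composition (A, C, G, T), summing to 1.
#' @param name motif name.
#' @return An object of class `PWM`.
#' @export
build_pwm <- function(sites, pseudocount = 1,
                      background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                      name = "motif") {
  if (length(sites) < 1) stop("need at least one site")
  w <- unique(nchar(sites))
  if (length(w) != 1) stop("sites have mixed lengths")
  mats <- strsplit(toupper(sites), "")
  if (!all(unlist(mats) %in% c("A", "C", "G", "T"))) {
    stop("sites contain non-ACGT characters")
  }
  counts <- matrix(0, 4, w, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (s in mats) {
    idx <- match(s, rownames(counts))
    counts[cbind(idx, seq_len(w))] <- counts[cbind(idx, seq_len(w))] + 1
  }
  pwm_from_counts(counts, pseudocount = pseudocount,
                  background = background, name = name)
}

#' Build a PWM from a 4 x w count matrix
#'
#' @param counts numeric 4 x w matrix, rows A, C, G, T.
#' @param pseudocount,background,name as in [build_pwm()].
#' @return An object of class `PWM`.
#' @export
pwm_from_counts <- function(counts, pseudocount = 1,
                            background = c(A = 0.25, C = 0.25,
                                           G = 0.25, T = 0.25),
                            name = "motif") {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4) stop("counts must have 4 rows (A, C, G, T)")
  if (any(counts < 0)) stop("negative counts")
  rownames(counts) <- c("A", "C", "G", "T")
  background <- background / sum(background)
  n <- colSums(counts)
  mat <- sweep(counts + pseudocount, 2, n + 4 * pseudocount, "/")
  if (any(mat <= 0)) {
    stop("zero probabilities; use a positive pseudocount")
  }
  stopifnot(all(abs(colSums(mat) - 1) < 1e-9))
  structure(list(name = name, mat = mat,
                 background = stats::setNames(background,
                                              c("A", "C", "G", "T")),
                 pseudocount = pseudocount),
            class = "PWM")
}

#' @export
print.PWM <- function(x, ...) {
  cat(sprintf("PWM '%s': width %d, max log-odds %.2f bits\n",
              x$name, ncol(x$mat), pwm_max_score(x)))
  invisible(x)
}

pwm_width <- function(pwm) ncol(pwm$mat)

# 5 x w log2-odds matrix; the N row contributes 0.
pwm_logodds <- function(pwm) {
  lo <- log2(pwm$mat / pwm$background)
  rbind(lo, N = 0)
}

pwm_logodds_revcomp <- function(lo) {
  w <- ncol(lo)
  out <- lo[c(4, 3, 2, 1, 5), w:1, drop = FALSE]
  rownames(out) <- rownames(lo)
  out
}

#' Maximum attainable log-odds score of a PWM
#' @param pwm a [build_pwm()] object.
#' @return scalar, bits.
#' @export
pwm_max_score <- function(pwm) {
  lo <- log2(pwm$mat / pwm$background)
  sum(apply(lo, 2, max))
}

#' Scan one sequence with a PWM on both strands
#'
#' Scores every offset on both strands with log2-odds against the PWM's
#' background and reports hits scoring at least
#' `threshold_frac * pwm_max_score(pwm)`. `N` positions contribute 0. A `-`
#' strand hit at offset `o` means the reverse complement of the motif matches
#' the forward sequence at `o` (offsets are leftmost window positions, 0-based
#' from the sequence start).
#'
#' @param sequence a single ACGTN string.
#' @param pwm a [build_pwm()] object.
#' @param threshold_frac hit threshold as a fraction of the maximum
#'   attainable score, in (0, 1].
#' @return data.frame with columns `offset`, `strand`, `score`, sorted by
#'   offset then strand (`+` before `-`). Sequences shorter than the motif
#'   yield zero rows.
#' @export
pwm_logodds_scan <- function(sequence, pwm, threshold_frac = 0.8) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  if (threshold_frac <= 0 || threshold_frac > 1) {
    stop("threshold_frac must be in (0, 1]")
  }
  codes <- seq_codes(sequence)
  lo <- pwm_logodds(pwm)
  thr <- threshold_frac * pwm_max_score(pwm)
  fwd <- cpp_window_scores(codes, lo)
  rev <- cpp_window_scores(codes, pwm_logodds_revcomp(lo))
  fi <- which(fwd >= thr)
  ri <- which(rev >= thr)
  hits <- data.frame(
    offset = c(fi, ri) - 1L,
    strand = rep(c("+", "-"), c(length(fi), length(ri))),
    score = c(fwd[fi], rev[ri]),
    stringsAsFactors = FALSE)
  hits <- hits[order(hits$offset, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Count PWM hits per sequence over a sequence set
#'
#' Batch counterpart of [pwm_logodds_scan()]: counts, for every sequence,
#' the windows on either strand scoring at least
#' `threshold_frac * pwm_max_score(pwm)`.
#'
#' @param ss sequences: character vector or `seq_set`.
#' @param pwm a [build_pwm()] object.
#' @param threshold_frac hit threshold fraction.
#' @return integer vector of hit counts, one per sequence.
#' @export
scan_hit_counts <- function(ss, pwm, threshold_frac = 0.8) {
  ss <- seqset(ss)
  lo <- pwm_logodds(pwm)
  thr <- threshold_frac * pwm_max_score(pwm)
  cpp_hit_counts(ss$codes, ss$ends, lo, pwm_logodds_revcomp(lo), thr)
}

#' Construct a background sequence set for enrichment testing
#'
#' `"dinucleotide-shuffle"` produces `n_bg_per_fg` shuffles of every
#' foreground sequence, each preserving that sequence's dinucleotide (and
#' hence mononucleotide) multiset. `"genomic-sample"` samples length-matched
#' windows uniformly from supplied genome sequences.
#'
#' @param fg foreground sequences: character vector or `seq_set`.
#' @param mode `"dinucleotide-shuffle"` or `"genomic-sample"`.
#' @param n_bg_per_fg background sequences per foreground sequence.
#' @param seed RNG seed (mandatory for reproducibility).
#' @param genome named character vector of chromosome sequences, required for
#'   `"genomic-sample"`.
#' @return a `seq_set` of `n_bg_per_fg * length(fg)` sequences.
#' @export
sample_background <- function(fg, mode = c("dinucleotide-shuffle",
                                           "genomic-sample"),
                              n_bg_per_fg = 10L, seed, genome = NULL) {
  mode <- match.arg(mode)
  if (missing(seed)) stop("seed is required")
  ss <- seqset(fg)
  if (seqset_n(ss) == 0) stop("empty foreground")
  set.seed(seed)
  lens <- seqset_lengths(ss)
  if (mode == "dinucleotide-shuffle") {
    big_codes <- rep(list(NULL), n_bg_per_fg)
    for (r in seq_len(n_bg_per_fg)) {
      big_codes[[r]] <- cpp_dinuc_shuffle(ss$codes, ss$ends)
    }
    out_lens <- rep(lens, times = n_bg_per_fg)
    nm <- paste0(rep(ss$names, times = n_bg_per_fg), "_shuf",
                 rep(seq_len(n_bg_per_fg), each = seqset_n(ss)))
    new_seqset(unlist(big_codes, use.names = FALSE), out_lens, nm)
  } else {
    if (is.null(genome)) stop("genomic-sample mode requires a genome")
    gss <- seqset(genome)
    glens <- seqset_lengths(gss)
    out_lens <- rep(lens, times = n_bg_per_fg)
    chrom <- sample.int(seqset_n(gss), length(out_lens), replace = TRUE,
                        prob = glens / sum(glens))
    if (any(out_lens > glens[chrom])) {
      stop("background window longer than sampled chromosome")
    }
    codes <- vector("list", length(out_lens))
    for (i in seq_along(out_lens)) {
      cv <- seqset_extract(gss, chrom[i])
      s0 <- sample.int(length(cv) - out_lens[i] + 1L, 1L)
      codes[[i]] <- cv[s0:(s0 + out_lens[i] - 1L)]
    }
    nm <- paste0("bg_", seq_along(out_lens))
    new_seqset(unlist(codes, use.names = FALSE), out_lens, nm)
  }
}

#' One-sided motif enrichment test (sequences with a hit, fg vs bg)
#'
#' Upper-tail hypergeometric test on the 2x2 table (with-hit / without-hit x
#' foreground / background). The fold change is the rate ratio
#' `(fg_with/fg_total) / (bg_with/bg_total)`, with a 0.5 continuity
#' correction on the background count when it is zero.
#'
#' @param fg_with_hit,fg_total,bg_with_hit,bg_total counts.
#' @param name motif name carried into the result.
#' @return one-row data.frame (`EnrichmentResult`): `motif`, `fg_with_hit`,
#'   `fg_total`, `bg_with_hit`, `bg_total`, `fold`, `p`.
#' @export
motif_enrichment_test <- function(fg_with_hit, fg_total, bg_with_hit,
                                  bg_total, name = "motif") {
  if (fg_total == 0 || bg_total == 0) stop("empty foreground or background")
  stopifnot(fg_with_hit >= 0, fg_with_hit <= fg_total,
            bg_with_hit >= 0, bg_with_hit <= bg_total)
  k_with <- fg_with_hit + bg_with_hit
  p <- stats::phyper(fg_with_hit - 1, k_with,
                     fg_total + bg_total - k_with, fg_total,
                     lower.tail = FALSE)
  bg_rate <- if (bg_with_hit == 0) 0.5 / bg_total else bg_with_hit / bg_total
  data.frame(motif = name, fg_with_hit = fg_with_hit, fg_total = fg_total,
             bg_with_hit = bg_with_hit, bg_total = bg_total,
             fold = (fg_with_hit / fg_total) / bg_rate, p = p,
             stringsAsFactors = FALSE)
}

#' Rank a motif library by enrichment in a sequence class
#'
#' Scans foreground and background with every motif, tests each with
#' [motif_enrichment_test()] and returns all motifs ordered by ascending p,
#' ties by descending fold then name. No significance filter is applied.
#'
#' @param fg foreground sequences (character or `seq_set`).
#' @param library list of [build_pwm()] objects.
#' @param bg background sequences (character or `seq_set`), e.g. from
#'   [sample_background()].
#' @param threshold_frac scanning threshold fraction.
#' @return data.frame of [motif_enrichment_test()] rows plus `rank`.
#' @export
rank_motifs <- function(fg, library, bg, threshold_frac = 0.8) {
  if (length(library) == 0) stop("empty motif library")
  fg <- seqset(fg)
  bg <- seqset(bg)
  rows <- lapply(library, function(pwm) {
    fgh <- sum(scan_hit_counts(fg, pwm, threshold_frac) > 0)
    bgh <- sum(scan_hit_counts(bg, pwm, threshold_frac) > 0)
    motif_enrichment_test(fgh, seqset_n(fg), bgh, seqset_n(bg),
                          name = pwm$name)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p, -out$fold, out$motif), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Read a motif library from a plain-text count-matrix file
#'
#' Format: one record per motif, a `>name` line followed by four lines
#' `A <counts>`, `C <counts>`, `G <counts>`, `T <counts>` (whitespace
#' separated, equal length). Matrices are converted to probabilities with
#' the given pseudocount.
#'
#' @param path motif file.
#' @param pseudocount,background passed to [pwm_from_counts()].
#' @return named list of `PWM` objects.
#' @export
read_motif_library <- function(path, pseudocount = 1,
                               background = c(A = 0.25, C = 0.25,
                                              G = 0.25, T = 0.25)) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  starts <- grep("^>", lines)
  if (length(starts) == 0) stop("no motif records in ", path)
  out <- list()
  for (k in seq_along(starts)) {
    i <- starts[k]
    name <- sub("^>\\s*", "", lines[i])
    if (i + 4 > length(lines)) stop("truncated motif record: ", name)
    rows <- lapply(lines[(i + 1):(i + 4)], function(l) {
      parts <- strsplit(l, "\\s+")[[1]]
      as.numeric(parts[-1])
    })
    bases <- vapply(lines[(i + 1):(i + 4)],
                    function(l) strsplit(l, "\\s+")[[1]][1], character(1))
    if (!identical(unname(bases), c("A", "C", "G", "T"))) {
      stop("motif ", name, ": rows must be A, C, G, T in order")
    }
    counts <- do.call(rbind, rows)
    out[[name]] <- pwm_from_counts(counts, pseudocount = pseudocount,
                                   background = background, name = name)
  }
  out
}

#' The bundled motif library
#'
#' Eight synthetic count matrices shipped with the package, modelled on the
#' consensus patterns of the motif families used throughout the analyses:
#' GATA (WGATAR), MEF2 (A/T-rich MADS box), NFY (CCAAT), SOX, HAND-class
#' E-box, CTCF-like, SP1-like (GC box) and RARA-like. They are test fixtures
#' encoding the families' consensus, not curated database matrices.
#'
#' @inheritParams read_motif_library
#' @return named list of `PWM` objects.
#' @export
default_motif_library <- function(pseudocount = 1,
                                  background = c(A = 0.25, C = 0.25,
                                                 G = 0.25, T = 0.25)) {
  path <- system.file("extdata", "motifs.txt", package = "pioneerscan",
                      mustWork = TRUE)
  read_motif_library(path, pseudocount = pseudocount, background = background)
}
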