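# Cohort statistics: positional clustering of damaging variants along the
# protein and genotype-phenotype association from patient tables.

#' One-sided binomial test for variant clustering in a protein window
#'
#' Under the null, each of `n` variants falls in a window of `w` of the `L`
#' residues independently with probability `q = w / L`; the test reports the
#' upper tail `P(X >= k)`.
#'
#' @param k variants observed in the window.
#' @param n total variants with a residue position.
#' @param w window length (amino acids).
#' @param L protein length (amino acids).
#' @return one-sided p-value.
#' @export
binomial_window_test <- function(k, n, w, L) {
  if (k < 0 || n < 0 || k > n) stop("need 0 <= k <= n")
  if (w < 1 || w > L) stop("need 1 <= w <= L")
  if (k == 0) return(1)
  stats::pbinom(k - 1, n, w / L, lower.tail = FALSE)
}

#' Exploratory sliding-window clustering scan
#'
#' Slides a fixed-width window along the protein, applies
#' [binomial_window_test()] at each offset and Bonferroni-corrects over the
#' number of windows. This is an exploratory mode: the primary analysis uses
#' a single pre-specified window.
#'
#' @param positions integer residue positions of the variants (NAs dropped).
#' @param w window width (amino acids).
#' @param L protein length.
#' @param step window step size.
#' @return data.frame with `start`, `end`, `k`, `p`, `p_bonferroni`.
#' @export
binomial_window_scan <- function(positions, w, L, step = 1L) {
  positions <- positions[!is.na(positions)]
  n <- length(positions)
  starts <- seq(1L, L - w + 1L, by = step)
  k <- vapply(starts, function(s) {
    sum(positions >= s & positions <= s + w - 1L)
  }, numeric(1))
  p <- vapply(k, binomial_window_test, numeric(1), n = n, w = w, L = L)
  data.frame(start = starts, end = starts + w - 1L, k = k, p = p,
             p_bonferroni = pmin(1, p * length(starts)))
}

#' Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric test. The two-sided p-value sums all tables with the
#' observed margins whose point probability does not exceed the observed
#' table's (minimum-likelihood rule, the convention used by R's
#' implementation, against which the result is cross-checked in the test
#' suite). The one-sided p-value is the upper tail for cell `a`. The odds
#' ratio is the sample odds ratio `(a d) / (b c)`, with a 0.5 continuity
#' correction added to every cell when any cell is zero.
#'
#' @param table 2x2 matrix or vector `c(a, b, c, d)` (row-wise).
#' @return list with `p_one_sided`, `p_two_sided`, `odds_ratio`, `table`.
#' @export
fisher_exact_2x2 <- function(table) {
  x <- as.numeric(table)
  if (length(x) != 4 || any(x < 0) || any(x != round(x))) {
    stop("table must be four non-negative integer cells")
  }
  a <- x[1]; b <- x[2]; c <- x[3]; d <- x[4]
  m <- a + b          # row 1 margin
  n2 <- c + d         # row 2 margin
  k <- a + c          # column 1 margin
  if (m + n2 == 0 || (k == 0 && b + d == 0)) stop("empty table")
  if (m == 0 || n2 == 0 || k == 0 || k == m + n2) {
    # a fixed margin is empty: only one table is possible
    return(list(p_one_sided = 1, p_two_sided = 1,
                odds_ratio = odds_ratio_2x2(a, b, c, d),
                table = matrix(x, 2, byrow = TRUE)))
  }
  support <- max(0, k - n2):min(k, m)
  probs <- stats::dhyper(support, m, n2, k)
  p_obs <- probs[match(a, support)]
  p_one <- sum(probs[support >= a])
  # minimum-likelihood rule with the same relative tolerance R uses
  p_two <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  list(p_one_sided = p_one, p_two_sided = p_two,
       odds_ratio = odds_ratio_2x2(a, b, c, d),
       table = matrix(x, 2, byrow = TRUE))
}

odds_ratio_2x2 <- function(a, b, c, d) {
  if (any(c(a, b, c, d) == 0)) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  (a * d) / (b * c)
}

#' Cohort summary of phenotype flags
#'
#' For each flag, counts and percentages overall and within each variant
#' class. Percentages are always computed from the counts, never stored.
#'
#' @param cohort a `CohortTable` (see [read_cohort()]).
#' @return data.frame with columns `flag`, `stratum`, `n`, `total`,
#'   `percent` (1 decimal).
#' @export
cohort_summary <- function(cohort) {
  stopifnot(inherits(cohort, "CohortTable"))
  if (nrow(cohort) == 0) stop("empty cohort")
  flags <- c("extracardiac", "pa_cdh", "neuro")
  rows <- list()
  for (fl in flags) {
    v <- cohort[[fl]]
    rows[[length(rows) + 1]] <- data.frame(
      flag = fl, stratum = "overall", n = sum(v), total = length(v))
    for (cls in c("LoF", "missense")) {
      sel <- cohort$variant_class == cls
      rows[[length(rows) + 1]] <- data.frame(
        flag = fl, stratum = cls, n = sum(v[sel]), total = sum(sel))
    }
  }
  out <- do.call(rbind, rows)
  out$percent <- round(100 * out$n / out$total, 1)
  out
}

#' Genotype-phenotype association from patient-level data
#'
#' Builds a 2x2 contingency table for a phenotype flag against a
#' stratification and applies [fisher_exact_2x2()]. Strata:
#' `"variant_class"` compares LoF vs missense carriers;
#' `"exon4_missense"` compares missense carriers with a residue position
#' inside the window (default 435-477, the exon-4 zinc-finger) against
#' missense carriers elsewhere (patients without a residue position are
#' excluded).
#'
#' @param cohort a `CohortTable`.
#' @param flag one of `"extracardiac"`, `"pa_cdh"`, `"neuro"`.
#' @param stratify_by `"variant_class"` or `"exon4_missense"`.
#' @param window integer c(start, end) residue window for `exon4_missense`.
#' @return list with `table` (2x2, rows = stratum yes/no, cols = flag
#'   yes/no), `fisher` ([fisher_exact_2x2()] result), `stratum_labels`.
#' @export
phenotype_association <- function(cohort, flag = c("extracardiac", "pa_cdh",
                                                   "neuro"),
                                  stratify_by = c("variant_class",
                                                  "exon4_missense"),
                                  window = c(435L, 477L)) {
  stopifnot(inherits(cohort, "CohortTable"))
  flag <- match.arg(flag)
  stratify_by <- match.arg(stratify_by)
  v <- cohort[[flag]]
  if (stratify_by == "variant_class") {
    in_stratum <- cohort$variant_class == "LoF"
    labels <- c("LoF", "missense")
  } else {
    mis <- cohort$variant_class == "missense" & !is.na(cohort$residue_position)
    cohort <- cohort[mis, , drop = FALSE]
    v <- v[mis]
    in_stratum <- cohort$residue_position >= window[1] &
      cohort$residue_position <= window[2]
    labels <- c(sprintf("missense %d-%d", window[1], window[2]),
                "missense elsewhere")
  }
  if (sum(in_stratum) == 0 || sum(!in_stratum) == 0) {
    stop("a stratum has zero patients")
  }
  tab <- matrix(c(sum(v & in_stratum), sum(!v & in_stratum),
                  sum(v & !in_stratum), sum(!v & !in_stratum)),
                nrow = 2, byrow = TRUE,
                dimnames = list(labels, c(flag, paste0("no_", flag))))
  list(table = tab, fisher = fisher_exact_2x2(as.vector(t(tab))),
       stratum_labels = labels)
}
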