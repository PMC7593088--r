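# Count normalization, per-peak differential occupancy (exact conditional
# Poisson test), per-gene differential expression and FDR control.

#' Library-size normalization
#'
#' Scales each sample's counts to the mean library size:
#' `normalized = count / lib_size * mean(lib_sizes)`.
#'
#' @param table a [count_table()].
#' @return list with `normalized` matrix and per-sample `factors`
#'   (`mean(lib) / lib`).
#' @export
normalize_libsize <- function(table) {
  stopifnot(inherits(table, "CountTable"))
  if (any(table$lib_sizes <= 0)) stop("zero or negative library size")
  factors <- mean(table$lib_sizes) / table$lib_sizes
  normalized <- sweep(table$counts, 2, factors, "*")
  list(normalized = normalized, factors = factors)
}

#' Exact two-sided Poisson rate-ratio test (conditional binomial)
#'
#' Under the null of equal rates, conditionally on `n = a + b`,
#' `a ~ Binomial(n, libsize_a / (libsize_a + libsize_b))`. The two-sided
#' p-value doubles the smaller tail (both tails include the observed count)
#' and is capped at 1. All arguments are vectorized.
#'
#' @param a,b counts in the two conditions.
#' @param libsize_a,libsize_b library sizes.
#' @return numeric vector of p-values; `a = b = 0` gives 1 (no evidence).
#' @export
poisson_diff_test <- function(a, b, libsize_a = 1, libsize_b = 1) {
  if (any(a < 0) || any(b < 0)) stop("counts must be non-negative")
  n <- a + b
  pr <- libsize_a / (libsize_a + libsize_b)
  lower <- stats::pbinom(a, n, pr)
  upper <- stats::pbinom(a - 1, n, pr, lower.tail = FALSE)
  p <- pmin(1, 2 * pmin(lower, upper))
  p[n == 0] <- 1
  p
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate control with monotonicity enforcement;
#' invariant to input order.
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @return adjusted p-values in input order.
#' @export
benjamini_hochberg <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Call differential peak occupancy between two conditions
#'
#' Counts are summed within each condition, tested per peak with
#' [poisson_diff_test()], adjusted with [benjamini_hochberg()], and called
#' `REDUCED` / `INCREASED` / `UNCHANGED` at the adjusted-p and fold-change
#' thresholds. `log2FC` is other vs reference on library-size-normalized
#' condition totals with a pseudocount of 1; "two fold" means
#' `|log2FC| >= log2(fc_min)`.
#'
#' @param table a [count_table()] over the union peak set.
#' @param reference,other condition labels in `table$condition`.
#' @param fc_min minimum fold change (default 2).
#' @param alpha adjusted-p threshold (default 1e-4).
#' @return data.frame with columns `peak_id`, `log2FC`, `p_raw`, `p_adj`,
#'   `call`, plus attribute `summary` (n_reduced, n_increased, fractions).
#' @export
call_differential_peaks <- function(table, reference, other,
                                    fc_min = 2, alpha = 1e-4) {
  stopifnot(inherits(table, "CountTable"))
  if (nrow(table$counts) == 0) stop("empty count table")
  cond <- as.character(table$condition)
  if (!reference %in% cond) stop("reference condition not in table: ", reference)
  if (!other %in% cond) stop("other condition not in table: ", other)
  ref_cols <- which(cond == reference)
  oth_cols <- which(cond == other)
  a <- rowSums(table$counts[, oth_cols, drop = FALSE])   # other
  b <- rowSums(table$counts[, ref_cols, drop = FALSE])   # reference
  la <- sum(table$lib_sizes[oth_cols])
  lb <- sum(table$lib_sizes[ref_cols])
  p_raw <- poisson_diff_test(a, b, la, lb)
  p_adj <- benjamini_hochberg(p_raw)
  mean_lib <- (la + lb) / 2
  log2fc <- log2(a / la * mean_lib + 1) - log2(b / lb * mean_lib + 1)
  lfc_min <- log2(fc_min)
  call <- rep("UNCHANGED", length(a))
  sig <- p_adj < alpha & abs(log2fc) >= lfc_min
  call[sig & log2fc <= -lfc_min] <- "REDUCED"
  call[sig & log2fc >= lfc_min] <- "INCREASED"
  out <- data.frame(peak_id = rownames(table$counts), log2FC = log2fc,
                    p_raw = p_raw, p_adj = p_adj, call = call,
                    flag_no_counts = (a + b) == 0,
                    stringsAsFactors = FALSE, row.names = NULL)
  n_red <- sum(call == "REDUCED")
  n_inc <- sum(call == "INCREASED")
  attr(out, "summary") <- list(
    n = nrow(out), n_reduced = n_red, n_increased = n_inc,
    frac_reduced = n_red / nrow(out), frac_increased = n_inc / nrow(out),
    reference = reference, other = other, fc_min = fc_min, alpha = alpha)
  out
}

#' Differential expression between two conditions
#'
#' Per-gene two-sample t test (pooled variance) on `log2(normalized + 1)`
#' when both conditions have at least two replicates; with a single
#' replicate in either condition it falls back to the exact conditional
#' binomial test on pooled counts. `log2FC` is condition b vs condition a
#' on mean normalized counts with a pseudocount of 1. Calls are `UP` /
#' `DOWN` / `NS` at the adjusted-p and |log2FC| thresholds; genes with all
#' zero counts are flagged and called `NS`.
#'
#' @param expr a [count_table()] of gene counts.
#' @param cond_a,cond_b condition labels (earlier and later time point).
#' @param alpha_de adjusted-p threshold.
#' @param lfc_min minimum |log2FC|.
#' @return data.frame with columns `gene_id`, `log2FC`, `p_raw`, `p_adj`,
#'   `call`, `flag_all_zero`.
#' @export
differential_expression <- function(expr, cond_a = "day4", cond_b = "day5",
                                    alpha_de = 0.05, lfc_min = 1) {
  stopifnot(inherits(expr, "CountTable"))
  cond <- as.character(expr$condition)
  if (!cond_a %in% cond) stop("condition not in table: ", cond_a)
  if (!cond_b %in% cond) stop("condition not in table: ", cond_b)
  ia <- which(cond == cond_a)
  ib <- which(cond == cond_b)
  norm <- normalize_libsize(expr)$normalized
  xa <- norm[, ia, drop = FALSE]
  xb <- norm[, ib, drop = FALSE]
  log2fc <- log2(rowMeans(xb) + 1) - log2(rowMeans(xa) + 1)
  all_zero <- rowSums(expr$counts[, c(ia, ib), drop = FALSE]) == 0
  if (length(ia) >= 2 && length(ib) >= 2) {
    la <- log2(xa + 1)
    lb <- log2(xb + 1)
    na <- ncol(la); nb <- ncol(lb)
    ma <- rowMeans(la); mb <- rowMeans(lb)
    va <- rowSums((la - ma)^2) / (na - 1)
    vb <- rowSums((lb - mb)^2) / (nb - 1)
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    tstat <- (mb - ma) / se
    df <- na + nb - 2
    p_raw <- 2 * stats::pt(-abs(tstat), df)
    # degenerate variance: identical replicates
    zero_se <- se == 0
    p_raw[zero_se & (mb == ma)] <- 1
    p_raw[zero_se & (mb != ma)] <- 0
  } else {
    a <- rowSums(expr$counts[, ib, drop = FALSE])
    b <- rowSums(expr$counts[, ia, drop = FALSE])
    p_raw <- poisson_diff_test(a, b, sum(expr$lib_sizes[ib]),
                               sum(expr$lib_sizes[ia]))
  }
  p_raw[all_zero] <- 1
  p_adj <- benjamini_hochberg(p_raw)
  call <- rep("NS", nrow(norm))
  sig <- p_adj < alpha_de & abs(log2fc) >= lfc_min & !all_zero
  call[sig & log2fc > 0] <- "UP"
  call[sig & log2fc < 0] <- "DOWN"
  data.frame(gene_id = rownames(expr$counts), log2FC = log2fc,
             p_raw = p_raw, p_adj = p_adj, call = call,
             flag_all_zero = all_zero,
             stringsAsFactors = FALSE, row.names = NULL)
}
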