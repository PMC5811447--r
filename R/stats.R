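#' Pearson chi-square test on a 2x2 contingency table
#'
#' Group contrasts of infiltration call counts use the plain Pearson
#' chi-square statistic with 1 degree of freedom (no continuity correction
#' by default; Yates available by flag).
#'
#' @param table 2x2 matrix of non-negative integer counts
#'   (called/not-called x group).
#' @param correction apply Yates continuity correction.
#' @return list with `table`, `chi2`, `df`, `p`.
#' @export
chi_square_2x2 <- function(table, correction = FALSE) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L)))
    stop_validation("`table` must be 2x2")
  if (any(table < 0) || any(table != round(table)))
    stop_validation("counts must be non-negative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop_degenerate("a margin of the 2x2 table is zero; consider Fisher's exact test")
  ht <- suppressWarnings(stats::chisq.test(table, correct = correction))
  list(table = table, chi2 = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Fold change of infiltration fractions with pseudocount
#'
#' `((called_a + pc) / (n_a + 2 pc)) / ((called_b + pc) / (n_b + 2 pc))`:
#' the Haldane-Anscombe pseudocount keeps the ratio finite and positive
#' when either group has zero (or full) calls.
#'
#' @param called_a,n_a calls and group size of the numerator group.
#' @param called_b,n_b calls and group size of the denominator group.
#' @param pseudocount added to each call count (default 0.5).
#' @return A positive finite ratio.
#' @export
fold_change <- function(called_a, n_a, called_b, n_b, pseudocount = 0.5) {
  pc <- pseudocount
  ((called_a + pc) / (n_a + 2 * pc)) / ((called_b + pc) / (n_b + 2 * pc))
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom and two-sided p, used for all cytokine and checkpoint panel
#' contrasts. Two identical degenerate groups (both variances zero, equal
#' means) return `t = 0, p = 1` rather than failing.
#'
#' @param x,y numeric values of the two groups (each n >= 2).
#' @return list with `t`, `df`, `p`, `mean_diff` (`mean(x) - mean(y)`).
#' @export
welch_t <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L)
    stop_degenerate("welch_t needs >= 2 observations per group")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y))
      return(list(t = 0, df = length(x) + length(y) - 2, p = 1,
                  mean_diff = 0))
    stop_degenerate("both variances are zero with unequal means")
  }
  ht <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_diff = mean(x) - mean(y))
}

#' Univariate simple linear regression
#'
#' Ordinary least squares of a gene's z-scores on the EMT score (or any
#' covariate); slope p-value from the two-sided t-test with n - 2 degrees
#' of freedom.
#'
#' @param x covariate (e.g. EMT scores), non-constant, n >= 3.
#' @param y response (e.g. a gene's z-scores), same length.
#' @return list with `slope`, `intercept`, `r2`, `p_slope`.
#' @export
simple_linreg <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop_degenerate("regression needs >= 3 points")
  if (stats::var(x) == 0) stop_degenerate("covariate is constant")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r2 = sm$r.squared,
       p_slope = unname(sm$coefficients[2L, 4L]))
}

#' Group contrast and EMT-score regression for a gene panel
#'
#' For each panel gene: Welch's t-test of z-scores in the `high` versus
#' `low` group, a simple linear regression of z-scores on the EMT score,
#' and Benjamini-Hochberg adjusted p-values alongside the raw ones (the
#' raw column reproduces the uncorrected per-gene convention; the BH
#' column the corrected one).
#'
#' @param m a z-scored [expression_matrix()].
#' @param groups tertile assignment from [stratify_tertiles()].
#' @param gene_panel character vector of gene symbols (absent genes are
#'   dropped with a warning).
#' @param emt_scores optional data.frame from [emt_score()]; when supplied,
#'   per-gene regressions on the EMT score are included.
#' @return data.frame with one row per gene: `gene`, `mean_high`,
#'   `mean_low`, `mean_diff`, `t`, `df`, `p`, `p_bh`, and (with scores)
#'   `slope`, `r2`, `p_slope`, `p_slope_bh`.
#' @export
panel_compare <- function(m, groups, gene_panel, emt_scores = NULL) {
  .check_zscored(m)
  if (!length(gene_panel)) stop_validation("empty gene panel")
  idx <- match_genes(gene_panel, rownames(m))
  if (anyNA(idx)) {
    warning(sprintf("dropping absent panel gene(s): %s",
                    paste(gene_panel[is.na(idx)], collapse = ", ")))
    gene_panel <- gene_panel[!is.na(idx)]
    idx <- idx[!is.na(idx)]
  }
  if (!length(idx)) stop_validation("no panel gene present in matrix")
  hi <- groups$sample_id[groups$label == "high"]
  lo <- groups$sample_id[groups$label == "low"]
  hi_j <- match(hi, colnames(m)); lo_j <- match(lo, colnames(m))
  hi_j <- hi_j[!is.na(hi_j)]; lo_j <- lo_j[!is.na(lo_j)]
  rows <- lapply(seq_along(idx), function(i) {
    zx <- as.numeric(m[idx[i], hi_j]); zy <- as.numeric(m[idx[i], lo_j])
    tt <- welch_t(zx, zy)
    out <- data.frame(gene = gene_panel[i], mean_high = mean(zx),
                      mean_low = mean(zy), mean_diff = tt$mean_diff,
                      t = tt$t, df = tt$df, p = tt$p,
                      stringsAsFactors = FALSE)
    if (!is.null(emt_scores)) {
      j <- match(emt_scores$sample_id, colnames(m))
      lr <- simple_linreg(emt_scores$score[!is.na(j)],
                          as.numeric(m[idx[i], j[!is.na(j)]]))
      out$slope <- lr$slope; out$r2 <- lr$r2; out$p_slope <- lr$p_slope
    }
    out
  })
  out <- do.call(rbind, rows)
  out$p_bh <- stats::p.adjust(out$p, method = "BH")
  if (!is.null(emt_scores))
    out$p_slope_bh <- stats::p.adjust(out$p_slope, method = "BH")
  out
}
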