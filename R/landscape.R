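#' Immune infiltration landscape by group
#'
#' For each immune cell type, compares the fraction of positively
#' infiltrating samples between the `high` ("mesenchymal") and `low`
#' ("epithelial") groups of a tertile assignment with a chi-square test on
#' call counts, and reports the low/high fold change of infiltration
#' fractions (Haldane-Anscombe pseudocount guarding zero counts). The `mid`
#' tertile is excluded from the contrast.
#'
#' @param calls output of [call_infiltration()].
#' @param groups data.frame from [stratify_tertiles()] or
#'   [single_gene_groups()].
#' @param pseudocount pseudocount for [fold_change()] (default 0.5).
#' @return data.frame with one row per cell type: `cell_type`, `n_high`,
#'   `n_low`, `called_high`, `called_low`, `frac_high`, `frac_low`,
#'   `fold_change` (low over high), `chi2`, `p`. `chi2`/`p` are `NA` with a
#'   warning when a margin of the 2x2 table is zero (all or no samples
#'   called in both groups).
#' @export
landscape <- function(calls, groups, pseudocount = 0.5) {
  keep <- groups$label %in% c("high", "low")
  groups <- groups[keep, , drop = FALSE]
  calls <- calls[calls$sample_id %in% groups$sample_id, , drop = FALSE]
  if (!nrow(calls))
    stop_validation("no overlap between calls and high/low groups")
  lab <- groups$label[match(calls$sample_id, groups$sample_id)]
  types <- unique(calls$cell_type)
  rows <- lapply(types, function(ct) {
    sel <- calls$cell_type == ct
    hi <- calls$call[sel & lab == "high"]
    lo <- calls$call[sel & lab == "low"]
    tab <- rbind(high = c(called = sum(hi), not = sum(!hi)),
                 low = c(called = sum(lo), not = sum(!lo)))
    stat <- tryCatch(chi_square_2x2(t(tab)),
                     emtscape_error = function(e) {
                       warning(sprintf("%s: %s", ct, conditionMessage(e)))
                       list(chi2 = NA_real_, p = NA_real_)
                     })
    data.frame(cell_type = ct, n_high = length(hi), n_low = length(lo),
               called_high = sum(hi), called_low = sum(lo),
               frac_high = mean(hi), frac_low = mean(lo),
               fold_change = fold_change(sum(lo), length(lo), sum(hi),
                                         length(hi), pseudocount),
               chi2 = stat$chi2, p = stat$p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
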