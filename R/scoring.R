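#' Per-sample EMT score
#'
#' The EMT score of a sample is the mean RNA-seq z-score of the mesenchymal
#' signature genes minus the mean z-score of the epithelial signature genes,
#' so mesenchymal-skewed samples score positive. The matrix must be
#' z-scored; raw matrices go through [zscore_normalize()] first.
#'
#' @param m a z-scored [expression_matrix()].
#' @param sig an [emt_signature()].
#' @param missing_gene_policy `"error"` fails if any signature gene is
#'   absent from the matrix; `"warn_drop"` warns and averages over the genes
#'   that are present (each arm must retain at least one gene).
#' @return data.frame with columns `sample_id`, `score`, `n_genes_used`.
#' @examples
#' m <- expression_matrix(
#'   matrix(0, 16, 3, dimnames = list(
#'     c(emt_signature()$epithelial, emt_signature()$mesenchymal),
#'     c("s1", "s2", "s3"))), is_zscored = TRUE)
#' emt_score(m)$score  # all zero
#' @export
emt_score <- function(m, sig = emt_signature(),
                      missing_gene_policy = c("error", "warn_drop")) {
  missing_gene_policy <- match.arg(missing_gene_policy)
  .check_zscored(m)
  epi <- .resolve_signature_genes(sig$epithelial, m, missing_gene_policy, "epithelial")
  mes <- .resolve_signature_genes(sig$mesenchymal, m, missing_gene_policy, "mesenchymal")
  score <- colMeans(m[mes, , drop = FALSE]) - colMeans(m[epi, , drop = FALSE])
  data.frame(sample_id = colnames(m), score = as.numeric(score),
             n_genes_used = length(epi) + length(mes),
             stringsAsFactors = FALSE)
}

#' Per-sample CD8 T-cell score
#'
#' Mean z-score of the four CD8 T-cell signature markers (CD8A, CD8B, IFNG,
#' PRF1). Stratify with [stratify_tertiles()] into high / intermediate /
#' low thirds.
#'
#' @inheritParams emt_score
#' @param genes CD8 signature genes; default [cd8_panel()].
#' @return data.frame with columns `sample_id`, `score`, `n_genes_used`.
#' @export
cd8_score <- function(m, genes = cd8_panel(),
                      missing_gene_policy = c("error", "warn_drop")) {
  missing_gene_policy <- match.arg(missing_gene_policy)
  .check_zscored(m)
  idx <- .resolve_signature_genes(genes, m, missing_gene_policy, "CD8 signature")
  score <- colMeans(m[idx, , drop = FALSE])
  data.frame(sample_id = colnames(m), score = as.numeric(score),
             n_genes_used = length(idx), stringsAsFactors = FALSE)
}

.check_zscored <- function(m) {
  if (!inherits(m, "ExpressionMatrix")) stop_validation("`m` must be an ExpressionMatrix")
  if (!is_zscored(m))
    stop_validation("scores are defined on z-scores; run zscore_normalize() first")
}

.resolve_signature_genes <- function(genes, m, policy, label) {
  idx <- match_genes(genes, rownames(m))
  if (anyNA(idx)) {
    absent <- genes[is.na(idx)]
    if (policy == "error")
      stop_validation(sprintf("%s gene(s) absent from matrix: %s",
                              label, paste(absent, collapse = ", ")))
    warning(sprintf("dropping absent %s gene(s): %s",
                    label, paste(absent, collapse = ", ")))
    idx <- idx[!is.na(idx)]
  }
  if (!length(idx))
    stop_validation(sprintf("no %s gene present in matrix", label))
  idx
}

#' Tertile stratification of sample scores
#'
#' Samples are sorted by score descending (ties broken by `sample_id`
#' ascending, so assignment is independent of input order) and split into
#' thirds: base size `floor(N/3)` per group, with the remainder allotted one
#' extra sample to `high` first, then `mid`. At N = 515 this yields
#' 172/172/171 and at N = 501 it yields 167/167/167, matching the cohort
#' splits the method was designed around.
#'
#' @param scores data.frame with `sample_id` and `score` columns (output of
#'   [emt_score()], [cd8_score()], or any per-sample score).
#' @param basis label recorded for the score the grouping is based on.
#' @return data.frame with columns `sample_id`, `label` (`"high"`, `"mid"`,
#'   `"low"`), `basis`, in the input's sample order.
#' @export
stratify_tertiles <- function(scores, basis = "score") {
  if (nrow(scores) < 3L) stop_degenerate("tertile split needs >= 3 samples")
  if (anyDuplicated(scores$sample_id))
    stop_validation("duplicate sample_id in scores")
  n <- nrow(scores)
  ord <- order(-scores$score, scores$sample_id, method = "radix")
  base <- n %/% 3L
  r <- n %% 3L
  sizes <- c(high = base + (r >= 1L), mid = base + (r >= 2L), low = base)
  label <- rep(c("high", "mid", "low"), times = sizes)
  out <- data.frame(sample_id = scores$sample_id[ord], label = label,
                    basis = basis, stringsAsFactors = FALSE)
  out[match(scores$sample_id, out$sample_id), , drop = FALSE] |>
    `rownames<-`(NULL)
}

#' Tertile groups on a single gene's expression
#'
#' High / mid / low thirds of the cohort by one gene's z-score, using the
#' same splitting rule as [stratify_tertiles()]. Used to study the immune
#' landscape of each signature gene individually.
#'
#' @param m a z-scored [expression_matrix()].
#' @param gene a gene symbol present in `m`.
#' @return data.frame as from [stratify_tertiles()], with `basis = gene`.
#' @export
single_gene_groups <- function(m, gene) {
  .check_zscored(m)
  idx <- match_genes(gene, rownames(m))
  if (is.na(idx)) stop_validation(sprintf("gene %s absent from matrix", gene))
  scores <- data.frame(sample_id = colnames(m), score = as.numeric(m[idx, ]),
                       stringsAsFactors = FALSE)
  stratify_tertiles(scores, basis = gene)
}
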