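#' Rank the genes of one sample
#'
#' Genes are ordered by z-score descending, ties broken by gene symbol
#' ascending (byte order), so the ranking is deterministic and independent
#' of matrix row order. Weights are `|z|^alpha`; `alpha = 0` gives the
#' unweighted (rank-only) Kolmogorov-Smirnov statistic.
#'
#' @param m a z-scored [expression_matrix()].
#' @param sample_id a sample present in `m`.
#' @param alpha weighting exponent (default 1, the classic weighted form).
#' @return data.frame with columns `gene`, `z`, `weight`, in rank order.
#' @export
rank_genes <- function(m, sample_id, alpha = 1) {
  .check_zscored(m)
  j <- match(sample_id, colnames(m))
  if (is.na(j)) stop_validation(sprintf("sample %s absent from matrix", sample_id))
  z <- as.numeric(m[, j])
  ord <- order(-z, rownames(m), method = "radix")
  data.frame(gene = rownames(m)[ord], z = z[ord],
             weight = abs(z[ord])^alpha, stringsAsFactors = FALSE)
}

#' Enrichment score of a gene set in a ranked list
#'
#' The classic weighted Kolmogorov-Smirnov running-sum statistic: walking
#' down the ranked list, hits increment the sum by `weight / sum(weights of
#' set genes)` and misses decrement it by `1 / (N - k)`; the score is the
#' signed maximum deviation of the sum from zero, in `[-1, 1]`. Positive
#' scores mean the set concentrates at the top of the ranking.
#'
#' @param ranked data.frame from [rank_genes()] (columns `gene`, `weight`).
#' @param gene_set character vector of gene symbols.
#' @return A single numeric enrichment score.
#' @export
enrichment_score <- function(ranked, gene_set) {
  pos <- which(!is.na(match_genes(ranked$gene, gene_set)))
  if (!length(pos))
    stop_degenerate("set not measurable: no gene of the set is in the ranked universe")
  .es_at_positions(pos, ranked$weight, nrow(ranked))
}

# ES from sorted hit positions; extremes of the running sum occur just
# after a hit (candidate maxima) or just before one (candidate minima).
# All-hit universes (k == N) degenerate to ES = 1 by convention.
.es_at_positions <- function(pos, weights, n) {
  k <- length(pos)
  if (k >= n) return(1)
  w <- weights[pos]
  W <- sum(w)
  # zero total hit weight (all z exactly 0 under alpha > 0): fall back to
  # equal weights, the alpha = 0 limit
  if (W <= 0) { w <- rep(1, k); W <- k }
  cw <- cumsum(w)
  miss <- (pos - seq_len(k)) / (n - k)   # misses seen before each hit
  after <- cw / W - miss                 # running sum just after hit i
  before <- c(0, cw[-k] / W) - miss      # just before hit i
  hi <- max(after, 0)
  lo <- min(before, 0)
  # exact ties between the extremes (common at alpha = 0) resolve to the
  # positive deviation; the 1e-12 slack absorbs summation-order rounding
  if (hi + lo >= -1e-12) hi else lo
}

#' Empirical permutation p-value for an enrichment score
#'
#' The null is gene-label permutation: random gene sets of the same size
#' are drawn from the measured universe and scored on the same ranking.
#' The one-sided p (positive infiltration) is
#' `(1 + #\{null ES >= observed\}) / (1 + n_perm)`, floored at
#' `1/(n_perm + 1)`.
#'
#' @inheritParams enrichment_score
#' @param n_perm number of permutations (>= 100; default 1000).
#' @param seed integer seed; required so calls are bit-reproducible.
#' @return list with `es`, `p_emp`, `n_perm`.
#' @export
permutation_pvalue <- function(ranked, gene_set, n_perm = 1000L, seed) {
  if (n_perm < 100L) stop_validation("n_perm must be >= 100 for a stable p-value")
  if (missing(seed)) stop_validation("a seed is required for the permutation null")
  es <- enrichment_score(ranked, gene_set)
  k <- sum(!is.na(match_genes(ranked$gene, gene_set)))
  null <- withr_seed(seed, .null_es(ranked$weight, nrow(ranked), k, n_perm))
  list(es = es, p_emp = (1 + sum(null >= es)) / (1 + n_perm), n_perm = n_perm)
}

# local seed scope without touching the caller's RNG stream
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# vector of n_perm null enrichment scores for random size-k sets; the
# running-sum extremes are evaluated for all permutations at once
# (columns = permutations), same arithmetic as .es_at_positions
.null_es <- function(weights, n, k, n_perm) {
  if (k >= n) return(rep(1, n_perm))
  pos <- vapply(seq_len(n_perm), function(b) sort.int(sample.int(n, k)),
                integer(k))
  pos <- matrix(pos, nrow = k)
  wm <- matrix(weights[pos], k, n_perm)
  W <- colSums(wm)
  zero <- W <= 0
  if (any(zero)) { wm[, zero] <- 1; W[zero] <- k }
  cw <- apply(wm, 2L, cumsum)
  cw <- matrix(cw, k, n_perm)
  miss <- (pos - seq_len(k)) / (n - k)
  after <- sweep(cw, 2L, W, "/") - miss
  before <- sweep(cw - wm, 2L, W, "/") - miss
  hi <- Reduce(pmax, asplit(after, 1L), rep(0, n_perm))
  lo <- Reduce(pmin, asplit(before, 1L), rep(0, n_perm))
  ifelse(hi + lo >= -1e-12, hi, lo)
}

#' Score every cell-type signature in every sample
#'
#' Single-sample enrichment over a gene-set collection: each sample is
#' ranked once and every set scored against that ranking; empirical p-values
#' come from a gene-label permutation null shared across sets of equal size
#' within a sample (the null depends only on the ranking and the set size).
#'
#' @param m a z-scored [expression_matrix()].
#' @param cell_sets a [gene_set_collection()] of immune metagene signatures.
#' @param alpha weighting exponent passed to [rank_genes()].
#' @param n_perm permutations per sample/set-size (default 1000).
#' @param seed integer seed for the permutation null.
#' @return data.frame in long form: `sample_id`, `cell_type`, `es`, `p_emp`.
#' @export
sample_enrichment <- function(m, cell_sets, alpha = 1, n_perm = 1000L, seed) {
  if (n_perm < 100L) stop_validation("n_perm must be >= 100 for a stable p-value")
  if (missing(seed)) stop_validation("a seed is required for the permutation null")
  .check_zscored(m)
  samples <- colnames(m)
  genes <- rownames(m)
  norm_univ <- norm_gene(genes)
  norm_sets <- lapply(cell_sets, norm_gene)
  n <- nrow(m)
  n_types <- length(cell_sets)
  es_all <- matrix(NA_real_, length(samples), n_types)
  p_all <- matrix(NA_real_, length(samples), n_types)
  withr_seed(seed, {
    for (si in seq_along(samples)) {
      z <- as.numeric(m[, si])
      ord <- order(-z, genes, method = "radix")
      w <- abs(z[ord])^alpha
      rank_of <- integer(n)
      rank_of[ord] <- seq_len(n)
      hits <- lapply(norm_sets, function(g) {
        pos <- rank_of[match(g, norm_univ)]
        sort.int(pos[!is.na(pos)])
      })
      ks <- lengths(hits)
      if (any(ks == 0L))
        stop_degenerate(sprintf("set not measurable: %s",
                                names(cell_sets)[which(ks == 0L)[1]]))
      es <- vapply(hits, .es_at_positions, numeric(1), weights = w, n = n)
      p <- numeric(n_types)
      for (k in unique(ks)) {
        null_k <- .null_es(w, n, k, n_perm)
        for (ci in which(ks == k))
          p[ci] <- (1 + sum(null_k >= es[ci])) / (1 + n_perm)
      }
      es_all[si, ] <- es
      p_all[si, ] <- p
    }
  })
  data.frame(sample_id = rep(samples, each = n_types),
             cell_type = rep(names(cell_sets), length(samples)),
             es = as.numeric(t(es_all)), p_emp = as.numeric(t(p_all)),
             stringsAsFactors = FALSE)
}

#' Infiltration calls at a false-discovery threshold
#'
#' Benjamini-Hochberg q-values are computed across the cell types within
#' each sample; a cell type is called positively infiltrating when its
#' enrichment score is positive and its q-value is at most `q_threshold`.
#'
#' @param results long data.frame from [sample_enrichment()] (columns
#'   `sample_id`, `cell_type`, `es`, `p_emp`); every sample must carry the
#'   same full complement of cell types.
#' @param q_threshold FDR threshold (default 0.10).
#' @param scope `"within_sample"` (default) adjusts across the cell types of
#'   each sample; `"global"` adjusts across all sample x set pairs.
#' @return The input with `q` and logical `call` columns appended.
#' @export
call_infiltration <- function(results, q_threshold = 0.10,
                              scope = c("within_sample", "global")) {
  scope <- match.arg(scope)
  need <- c("sample_id", "cell_type", "es", "p_emp")
  if (!all(need %in% names(results)))
    stop_validation("results must have sample_id, cell_type, es, p_emp")
  tab <- table(results$sample_id)
  if (length(unique(tab)) != 1L)
    stop_validation("every sample must be evaluated for the same cell types")
  if (scope == "global") {
    results$q <- stats::p.adjust(results$p_emp, method = "BH")
  } else {
    results$q <- stats::ave(results$p_emp, results$sample_id,
                            FUN = function(p) stats::p.adjust(p, method = "BH"))
  }
  results$call <- results$es > 0 & results$q <= q_threshold
  results
}

#' Wide boolean call matrix
#'
#' @param calls output of [call_infiltration()].
#' @return logical matrix, samples in rows, cell types in columns.
#' @export
call_matrix <- function(calls) {
  samples <- unique(calls$sample_id)
  types <- unique(calls$cell_type)
  mat <- matrix(FALSE, length(samples), length(types),
                dimnames = list(samples, types))
  mat[cbind(match(calls$sample_id, samples),
            match(calls$cell_type, types))] <- calls$call
  mat
}
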