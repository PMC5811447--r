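#' Expression matrix container
#'
#' A light S3 container for a gene x sample numeric matrix, the universe on
#' which all EMT and enrichment scores are computed. Values are either
#' cohort-relative RNA-seq z-scores (`is_zscored = TRUE`) or raw expression
#' to be normalised with [zscore_normalize()].
#'
#' @param values numeric matrix, genes in rows, samples in columns.
#' @param gene_ids character vector of unique gene symbols (defaults to
#'   `rownames(values)`).
#' @param sample_ids character vector of unique sample identifiers (defaults
#'   to `colnames(values)`).
#' @param is_zscored logical flag; scoring functions require `TRUE`.
#' @return An object of class `ExpressionMatrix`: the numeric matrix with
#'   gene/sample dimnames and an `is_zscored` attribute.
#' @examples
#' m <- expression_matrix(matrix(rnorm(6), 3, 2,
#'   dimnames = list(c("A", "B", "C"), c("s1", "s2"))), is_zscored = TRUE)
#' dim(m)
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values),
                              is_zscored = FALSE) {
  if (!is.matrix(values) || !is.numeric(values))
    stop_validation("`values` must be a numeric matrix")
  if (is.null(gene_ids) || is.null(sample_ids))
    stop_validation("gene and sample identifiers are required")
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(values) || length(sample_ids) != ncol(values))
    stop_validation("identifier lengths do not match matrix dimensions")
  if (anyDuplicated(gene_ids))
    stop_validation(sprintf("duplicate gene ids: %s",
      paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", ")))
  if (anyDuplicated(sample_ids))
    stop_validation(sprintf("duplicate sample ids: %s",
      paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", ")))
  if (any(is.infinite(values)))
    stop_validation("expression values must be finite or NA")
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(values, is_zscored = isTRUE(is_zscored),
            class = c("ExpressionMatrix", "matrix", "array"))
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples (%s)\n",
              nrow(x), ncol(x),
              if (is_zscored(x)) "z-scored" else "raw"))
  invisible(x)
}

#' @rdname expression_matrix
#' @param m an `ExpressionMatrix`.
#' @export
is_zscored <- function(m) isTRUE(attr(m, "is_zscored"))

#' Read a gene x sample expression matrix from TSV
#'
#' Expects a tab-separated file whose first column holds gene symbols and
#' whose header row holds sample identifiers. Duplicate gene symbols are
#' collapsed to the row with the highest variance (the usual cBioPortal
#' convention) with a warning; missing cells are handled per
#' `missing_policy`.
#'
#' @param path path to a TSV file.
#' @param missing_policy `"drop_gene"` drops genes with any missing value
#'   (warning states how many); `"error"` fails on the first missing value.
#' @param is_zscored whether the file already contains z-scores.
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path,
                                   missing_policy = c("drop_gene", "error"),
                                   is_zscored = TRUE) {
  missing_policy <- match.arg(missing_policy)
  if (!file.exists(path)) stop_input(sprintf("no such file: %s", path))
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (length(header) < 2L)
    stop_format("malformed header: expected a gene column plus >=1 sample column")
  sample_ids <- header[-1]
  if (anyDuplicated(sample_ids))
    stop_validation(sprintf("duplicated sample column(s): %s",
      paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", ")))
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) != length(header)) stop_format("ragged rows in expression TSV")
  genes <- trimws(as.character(df[[1]]))
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(vals)) {
    suppressWarnings(storage.mode(vals) <- "double")
  }
  rownames(vals) <- genes

  # collapse duplicated symbols to the highest-variance row
  if (anyDuplicated(norm_gene(genes))) {
    key <- norm_gene(genes)
    v <- apply(vals, 1L, stats::var, na.rm = TRUE)
    v[is.na(v)] <- -Inf
    keep <- unlist(lapply(split(seq_along(key), key)[unique(key)],
                          function(idx) idx[which.max(v[idx])]),
                   use.names = FALSE)
    keep <- sort(keep)
    warning(sprintf("collapsed %d duplicated gene symbol(s) to highest-variance row",
                    length(genes) - length(keep)))
    vals <- vals[keep, , drop = FALSE]
    genes <- genes[keep]
  }

  bad <- which(rowSums(!is.finite(vals) | is.na(vals)) > 0L)
  if (length(bad)) {
    if (missing_policy == "error")
      stop_validation(sprintf("missing/non-finite values in %d gene row(s), e.g. %s",
                              length(bad), genes[bad[1]]))
    warning(sprintf("dropped %d gene(s) with missing values", length(bad)))
    vals <- vals[-bad, , drop = FALSE]
    genes <- genes[-bad]
  }
  expression_matrix(vals, genes, sample_ids, is_zscored = is_zscored)
}

#' Write an expression matrix to TSV
#'
#' Values are printed at full precision (17 significant digits) so that
#' `read_expression_matrix(write_expression_matrix(m))` round-trips exactly.
#'
#' @param m an [expression_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path) {
  if (!inherits(m, "ExpressionMatrix")) stop_validation("`m` must be an ExpressionMatrix")
  if (nrow(m) == 0L || ncol(m) == 0L) stop_validation("refusing to write an empty matrix")
  con <- tryCatch(file(path, open = "wb"), error = function(e)
    .stop("emtscape_io_error", sprintf("cannot open %s for writing: %s",
                                       path, conditionMessage(e))))
  on.exit(close(con))
  writeLines(paste(c("gene", colnames(m)), collapse = "\t"), con)
  body <- vapply(seq_len(nrow(m)), function(i)
    paste(c(rownames(m)[i], sprintf("%.17g", m[i, ])), collapse = "\t"),
    character(1))
  writeLines(body, con)
  invisible(path)
}

#' Z-score normalise an expression matrix by gene
#'
#' Per gene, subtracts the mean across samples and divides by the sample
#' standard deviation (n - 1 denominator). Constant genes become all-zero
#' rows with a warning. Scores in this package are defined on z-scores, so
#' raw matrices must pass through this before scoring.
#'
#' @param m an [expression_matrix()] with `is_zscored = FALSE` semantics
#'   (a z-scored input is accepted and renormalised, which is a no-op up to
#'   numerical tolerance).
#' @return An [expression_matrix()] with `is_zscored = TRUE`.
#' @export
zscore_normalize <- function(m) {
  if (!inherits(m, "ExpressionMatrix")) stop_validation("`m` must be an ExpressionMatrix")
  if (ncol(m) < 2L) stop_degenerate("z-scoring needs at least 2 samples")
  mu <- rowMeans(m)
  sd <- apply(m, 1L, stats::sd)
  zero <- sd == 0 | !is.finite(sd)
  if (any(zero)) {
    warning(sprintf("%d constant gene(s) set to all-zero z-scores", sum(zero)))
    sd[zero] <- 1
  }
  z <- (unclass(m) - mu) / sd
  z[zero, ] <- 0
  expression_matrix(z, rownames(m), colnames(m), is_zscored = TRUE)
}
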