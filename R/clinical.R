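#' Read a clinical table with overall survival data
#'
#' Expects a tab-separated file with header columns `sample_id`, `os_time`
#' (days, non-negative) and `os_event` (1 = death observed, 0 = censored).
#' Rows with missing `os_time` are dropped with the count reported, which is
#' why survival n is typically smaller than the expression-cohort n.
#'
#' @param path path to a TSV file.
#' @return data.frame with columns `sample_id`, `os_time`, `os_event`.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("no such file: %s", path))
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "os_time", "os_event")
  if (!all(need %in% names(df)))
    stop_format(sprintf("clinical table must have columns %s",
                        paste(need, collapse = ", ")))
  df <- df[, need]
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop_validation("duplicate sample_id in clinical table")
  miss <- is.na(df$os_time)
  if (any(miss)) {
    message(sprintf("read_clinical: dropped %d row(s) with missing os_time",
                    sum(miss)))
    df <- df[!miss, , drop = FALSE]
  }
  if (any(df$os_time < 0)) stop_validation("os_time must be >= 0")
  if (any(is.na(df$os_event)) || !all(df$os_event %in% c(0, 1)))
    stop_validation("os_event must be 0 (censored) or 1 (death)")
  rownames(df) <- NULL
  df
}

#' Write a clinical table to TSV
#'
#' @param clinical data.frame as returned by [read_clinical()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(clinical, path) {
  utils::write.table(clinical[, c("sample_id", "os_time", "os_event")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
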