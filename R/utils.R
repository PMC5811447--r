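# internal helpers shared across modules

# classed conditions so the CLI can map error families to exit codes
.stop <- function(class, msg, call. = FALSE) {
  cond <- structure(
    class = c(class, "emtscape_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  )
  stop(cond)
}

stop_format     <- function(msg) .stop("emtscape_format_error", msg)
stop_validation <- function(msg) .stop("emtscape_validation_error", msg)
stop_input      <- function(msg) .stop("emtscape_input_error", msg)
stop_degenerate <- function(msg) .stop("emtscape_degenerate_error", msg)

# gene symbols are matched case-insensitively after trimming whitespace
norm_gene <- function(x) toupper(trimws(x))

# positions of `genes` in `universe` under normalised matching; NA if absent
match_genes <- function(genes, universe) {
  match(norm_gene(genes), norm_gene(universe))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
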