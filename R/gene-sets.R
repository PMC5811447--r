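#' Gene set collections and the packaged EMT signature
#'
#' Gene sets are stored as a named list of character vectors with a parallel
#' `descriptions` attribute — the shape the Broad GMT format encodes.
#'
#' @name gene_sets
NULL

#' Construct a gene set collection
#'
#' @param sets named list of character vectors (gene symbols).
#' @param descriptions optional character vector parallel to `sets`.
#' @return A `GeneSetCollection` (named list with descriptions attribute).
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop_validation("set names must be present and unique")
  if (any(lengths(sets) == 0L))
    stop_validation("every gene set must be non-empty")
  sets <- lapply(sets, function(g) {
    g <- trimws(as.character(g))
    g[!duplicated(norm_gene(g))]
  })
  descriptions <- descriptions %||% rep("", length(sets))
  names(descriptions) <- names(sets)
  structure(sets, descriptions = descriptions,
            class = c("GeneSetCollection", "list"))
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  cat(sprintf("GeneSetCollection: %d set(s), %d-%d genes each\n",
              length(x), min(lengths(x)), max(lengths(x))))
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' Broad dialect: one set per line, `name TAB description TAB gene TAB ...`.
#' Duplicate genes within a set are removed with a warning.
#'
#' @param path path to a GMT file.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("no such file: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning(sprintf("empty GMT file: %s", path))
    return(structure(stats::setNames(list(), character(0)),
                     descriptions = stats::setNames(character(0), character(0)),
                     class = c("GeneSetCollection", "list")))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop_format(sprintf("GMT line %d has %d field(s); need name, description, >=1 gene",
                        short[1], lengths(fields)[short[1]]))
  names_ <- vapply(fields, `[[`, character(1), 1L)
  descs <- vapply(fields, `[[`, character(1), 2L)
  sets <- lapply(fields, function(f) trimws(f[-c(1L, 2L)]))
  ndup <- sum(vapply(sets, function(g) sum(duplicated(norm_gene(g))), integer(1)))
  if (ndup > 0L)
    warning(sprintf("removed %d duplicate gene(s) within set(s)", ndup))
  names(sets) <- names_
  gene_set_collection(sets, descs)
}

#' Write gene sets to a GMT file
#'
#' @param sets a [gene_set_collection()] or plain named list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  descs <- attr(sets, "descriptions") %||% rep("", length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descs[[i]], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' The 16-gene canonical EMT marker signature
#'
#' Three epithelial markers (CDH1, DSP, TJP1 — TJP1 standing in for OCLN,
#' for which TCGA z-scores were unavailable in the source cohorts) and 13
#' mesenchymal markers. The EMT score is the mean mesenchymal z-score minus
#' the mean epithelial z-score, so epithelial-skewed samples score negative.
#'
#' @param epithelial,mesenchymal optional replacement gene lists; the two
#'   arms must be disjoint and non-empty.
#' @return An `EmtSignature`: list with `epithelial` and `mesenchymal`
#'   character vectors.
#' @examples
#' sig <- emt_signature()
#' lengths(sig)
#' @export
emt_signature <- function(epithelial = NULL, mesenchymal = NULL) {
  epithelial <- epithelial %||% c("CDH1", "DSP", "TJP1")
  mesenchymal <- mesenchymal %||% c(
    "VIM", "CDH2", "FOXC2", "SNAI1", "SNAI2", "TWIST1", "FN1",
    "ITGB6", "MMP2", "MMP3", "MMP9", "SOX10", "GSC"
  )
  epithelial <- unique(trimws(as.character(epithelial)))
  mesenchymal <- unique(trimws(as.character(mesenchymal)))
  if (!length(epithelial) || !length(mesenchymal))
    stop_validation("both signature arms must be non-empty")
  if (length(intersect(norm_gene(epithelial), norm_gene(mesenchymal))))
    stop_validation("epithelial and mesenchymal arms must be disjoint")
  structure(list(epithelial = epithelial, mesenchymal = mesenchymal),
            class = "EmtSignature")
}

#' Load the packaged EMT signature GMT fixture
#'
#' @return An [emt_signature()] read from the shipped GMT file with sets
#'   `EMT_EPITHELIAL` and `EMT_MESENCHYMAL`.
#' @export
emt_signature_fixture <- function() {
  path <- system.file("extdata", "emt_signature.gmt", package = "emtscape",
                      mustWork = TRUE)
  sets <- read_gmt(path)
  emt_signature(epithelial = sets[["EMT_EPITHELIAL"]],
                mesenchymal = sets[["EMT_MESENCHYMAL"]])
}

#' Default analysis panels
#'
#' `cytokine_panel()`: 16 immunosuppressive and inflammatory cytokines.
#' `checkpoint_panel()`: six immune checkpoint receptors/ligands plus FASLG.
#' `cd8_panel()`: the four CD8 T-cell signature markers whose mean z-score
#' is the CD8 T-cell score.
#'
#' @return Character vector of gene symbols.
#' @export
cytokine_panel <- function() {
  c("IFNA1", "IFNB1", "IFNG", "TNF", "TGFB1", "IL1A", "IL1B", "IL2",
    "IL3", "IL4", "IL5", "IL6", "CXCL8", "IL10", "IL12A", "IL12B")
}

#' @rdname cytokine_panel
#' @export
checkpoint_panel <- function() {
  c("CD274", "CTLA4", "HAVCR2", "ICOS", "TNFRSF4", "TNFRSF9", "FASLG")
}

#' @rdname cytokine_panel
#' @export
cd8_panel <- function() c("CD8A", "CD8B", "IFNG", "PRF1")

#' Default immune cell type names for the synthetic metagene collection
#'
#' 31 immune cell types, mirroring the dimensionality of published immune
#' metagene compendia. Cell types tagged `anti_tumor` couple negatively to
#' the latent EMT axis in the generator (immune exclusion); `pro_tumor`
#' types couple positively; the rest are neutral.
#'
#' @return data.frame with columns `cell_type` and `role`.
#' @export
immune_cell_types <- function() {
  anti <- c("Activated_CD8_T_cell", "Activated_CD4_T_cell",
            "Effector_memory_CD8_T_cell", "Effector_memory_CD4_T_cell",
            "Th17_cell", "Mature_dendritic_cell", "Th1_cell")
  pro <- c("Regulatory_T_cell", "Activated_B_cell", "Gamma_delta_T_cell",
           "Macrophage_M2", "MDSC")
  neutral <- c("Central_memory_CD8_T_cell", "Central_memory_CD4_T_cell",
               "Follicular_helper_T_cell", "Th2_cell", "NK_cell",
               "CD56bright_NK_cell", "CD56dim_NK_cell", "NKT_cell",
               "Immature_B_cell", "Memory_B_cell", "Plasma_cell",
               "Immature_dendritic_cell", "Plasmacytoid_dendritic_cell",
               "Macrophage_M1", "Monocyte", "Neutrophil", "Eosinophil",
               "Mast_cell", "Basophil")
  data.frame(
    cell_type = c(anti, pro, neutral),
    role = c(rep("anti_tumor", length(anti)), rep("pro_tumor", length(pro)),
             rep("neutral", length(neutral))),
    stringsAsFactors = FALSE
  )
}
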