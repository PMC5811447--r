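#' Pipeline configuration
#'
#' Loads (from YAML) or validates a pipeline configuration: input paths,
#' output directory and the analysis parameters. All randomness in a run
#' flows from the single `seed`; stochastic stages refuse to run without
#' one.
#'
#' @param config path to a YAML file or a named list with elements
#'   `paths` (expression, clinical, emt_gmt, immune_gmt, out_dir) and
#'   `params` (q_threshold, n_perm, seed, alpha, panels, simulate ...).
#' @return A validated `PipelineConfig` list.
#' @export
pipeline_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_input(sprintf("no such config file: %s", config))
    config <- yaml::read_yaml(config)
  }
  paths <- config$paths %||% list()
  params <- config$params %||% list()
  params$q_threshold <- params$q_threshold %||% 0.10
  if (params$q_threshold <= 0 || params$q_threshold > 1)
    stop_validation("q_threshold must be in (0, 1]")
  params$n_perm <- as.integer(params$n_perm %||% 1000L)
  params$alpha <- params$alpha %||% 1
  params$cytokine_panel <- params$cytokine_panel %||% cytokine_panel()
  params$checkpoint_panel <- params$checkpoint_panel %||% checkpoint_panel()
  params$cd8_cell_type <- params$cd8_cell_type %||% "Activated_CD8_T_cell"
  paths$out_dir <- paths$out_dir %||% "emtscape_out"
  structure(list(paths = paths, params = params,
                 simulate = config$simulate %||% list()),
            class = "PipelineConfig")
}

.require_seed <- function(cfg) {
  seed <- cfg$params$seed
  if (is.null(seed))
    stop_validation("config has no seed; refusing to run a stochastic stage")
  as.integer(seed)
}

.require_path <- function(cfg, what) {
  p <- cfg$paths[[what]]
  if (is.null(p)) stop_input(sprintf("config paths.%s is not set", what))
  if (!file.exists(p)) stop_input(sprintf("input not found: %s", p))
  p
}

.out_file <- function(cfg, name) {
  dir.create(cfg$paths$out_dir, showWarnings = FALSE, recursive = TRUE)
  file.path(cfg$paths$out_dir, name)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Pipeline stages
#'
#' Command-style wrappers that compose the package's operations into file-in
#' / file-out stages, mirroring the subcommands of the shipped CLI script
#' (`system.file("cli", "emtscape", package = "emtscape")`).
#'
#' * `cmd_simulate()` writes a synthetic cohort (expression TSV, clinical
#'   TSV, immune metagene GMT, ground-truth tables).
#' * `cmd_score()` computes EMT and CD8 scores with tertile labels.
#' * `cmd_landscape()` computes infiltration calls and the per-cell-type
#'   high-vs-low contrast table.
#' * `cmd_panels()` contrasts the cytokine and checkpoint panels.
#' * `cmd_survival()` runs the 2-group and 4-group log-rank analyses.
#' * `cmd_all()` runs score, landscape, panels and survival, and writes a
#'   JSON report plus a run manifest (config hash, input checksums, seed).
#'
#' @param cfg a [pipeline_config()].
#' @return Each stage returns its main result invisibly and writes its
#'   outputs under `paths.out_dir`.
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
cmd_simulate <- function(cfg) {
  cfg <- pipeline_config(cfg)
  seed <- .require_seed(cfg)
  sim_args <- cfg$simulate
  sim_args$seed <- seed
  sim <- generate_cohort(do.call(simulation_config, sim_args))
  write_expression_matrix(sim$expression, .out_file(cfg, "expression.tsv"))
  write_clinical(sim$clinical, .out_file(cfg, "clinical.tsv"))
  write_gmt(sim$cell_sets, .out_file(cfg, "immune_metagenes.gmt"))
  .write_tsv(data.frame(sample_id = names(sim$truth$latent_emt),
                        latent_emt = as.numeric(sim$truth$latent_emt),
                        true_group = sim$truth$true_groups$label),
             .out_file(cfg, "truth_latent.tsv"))
  infil <- data.frame(sample_id = rownames(sim$truth$infiltration),
                      sim$truth$infiltration, check.names = FALSE)
  .write_tsv(infil, .out_file(cfg, "truth_infiltration.tsv"))
  message(sprintf("simulated %d samples x %d genes (seed %d)",
                  ncol(sim$expression), nrow(sim$expression), seed))
  invisible(sim)
}

#' @rdname pipeline
#' @export
cmd_score <- function(cfg) {
  cfg <- pipeline_config(cfg)
  m <- read_expression_matrix(.require_path(cfg, "expression"))
  sig <- if (!is.null(cfg$paths$emt_gmt)) {
    sets <- read_gmt(.require_path(cfg, "emt_gmt"))
    emt_signature(sets[["EMT_EPITHELIAL"]], sets[["EMT_MESENCHYMAL"]])
  } else emt_signature()
  emt <- emt_score(m, sig)
  groups <- stratify_tertiles(emt, basis = "emt_score")
  cd8 <- cd8_score(m)
  cd8_groups <- stratify_tertiles(cd8, basis = "cd8_score")
  .write_tsv(cbind(emt[, c("sample_id", "score")],
                   label = groups$label),
             .out_file(cfg, "emt_scores.tsv"))
  .write_tsv(cbind(cd8[, c("sample_id", "score")],
                   label = cd8_groups$label),
             .out_file(cfg, "cd8_scores.tsv"))
  sizes <- table(factor(groups$label, c("high", "mid", "low")))
  message(sprintf("EMT groups: high (mesenchymal) n=%d, mid n=%d, low (epithelial) n=%d",
                  sizes["high"], sizes["mid"], sizes["low"]))
  invisible(list(emt = emt, groups = groups, cd8 = cd8,
                 cd8_groups = cd8_groups, matrix = m, signature = sig))
}

#' @rdname pipeline
#' @export
cmd_landscape <- function(cfg) {
  cfg <- pipeline_config(cfg)
  seed <- .require_seed(cfg)
  sc <- cmd_score(cfg)
  cell_sets <- read_gmt(.require_path(cfg, "immune_gmt"))
  enr <- sample_enrichment(sc$matrix, cell_sets, alpha = cfg$params$alpha,
                           n_perm = cfg$params$n_perm, seed = seed)
  calls <- call_infiltration(enr, q_threshold = cfg$params$q_threshold)
  land <- landscape(calls, sc$groups)
  .write_tsv(calls, .out_file(cfg, "infiltration_calls.tsv"))
  cm <- call_matrix(calls)
  .write_tsv(data.frame(sample_id = rownames(cm), cm, check.names = FALSE),
             .out_file(cfg, "call_matrix.tsv"))
  .write_tsv(land, .out_file(cfg, "landscape.tsv"))
  message(sprintf("landscape: %d cell types, %d significant at p<0.05",
                  nrow(land), sum(land$p < 0.05, na.rm = TRUE)))
  invisible(list(scores = sc, calls = calls, landscape = land))
}

#' @rdname pipeline
#' @export
cmd_panels <- function(cfg, scores = NULL) {
  cfg <- pipeline_config(cfg)
  sc <- scores %||% cmd_score(cfg)
  cyto <- panel_compare(sc$matrix, sc$groups, cfg$params$cytokine_panel,
                        emt_scores = sc$emt)
  ckpt <- panel_compare(sc$matrix, sc$groups, cfg$params$checkpoint_panel,
                        emt_scores = sc$emt)
  .write_tsv(cyto, .out_file(cfg, "cytokine_panel.tsv"))
  .write_tsv(ckpt, .out_file(cfg, "checkpoint_panel.tsv"))
  invisible(list(cytokine = cyto, checkpoint = ckpt))
}

#' @rdname pipeline
#' @param calls optional precomputed [call_infiltration()] output (used by
#'   `cmd_survival` for the 4-group analysis).
#' @param scores optional precomputed `cmd_score()` result to reuse.
#' @export
cmd_survival <- function(cfg, scores = NULL, calls = NULL) {
  cfg <- pipeline_config(cfg)
  clinical <- read_clinical(.require_path(cfg, "clinical"))
  sc <- scores %||% cmd_score(cfg)
  res <- emt_survival_analysis(clinical, sc$groups, calls = calls,
                               cd8_cell_type = cfg$params$cd8_cell_type)
  two <- res$two_group$test
  summ <- data.frame(analysis = "emt_2group", chi2 = two$chi2, df = two$df,
                     p = two$p, n = res$n_used)
  if (!is.null(res$four_group$test)) {
    four <- res$four_group$test
    summ <- rbind(summ, data.frame(analysis = "emt_cd8_4group",
                                   chi2 = four$chi2, df = four$df,
                                   p = four$p, n = sum(res$four_group$n)))
  }
  .write_tsv(summ, .out_file(cfg, "survival_tests.tsv"))
  curves <- res$two_group$curves
  km <- do.call(rbind, lapply(names(curves), function(g)
    cbind(group = g, as.data.frame(curves[[g]]))))
  .write_tsv(km, .out_file(cfg, "km_curves.tsv"))
  message(sprintf("log-rank mesenchymal vs epithelial: chi2=%.3f, p=%.4f",
                  two$chi2, two$p))
  invisible(res)
}

#' @rdname pipeline
#' @export
cmd_all <- function(cfg) {
  cfg <- pipeline_config(cfg)
  seed <- .require_seed(cfg)
  land <- cmd_landscape(cfg)
  panels <- cmd_panels(cfg, scores = land$scores)
  surv <- cmd_survival(cfg, scores = land$scores, calls = land$calls)
  report <- list(
    n_samples = ncol(land$scores$matrix),
    emt_group_sizes = as.list(table(land$scores$groups$label)),
    n_cell_types = nrow(land$landscape),
    landscape_significant = sum(land$landscape$p < 0.05, na.rm = TRUE),
    survival_p_2group = surv$two_group$test$p,
    survival_p_4group = if (!is.null(surv$four_group$test))
      surv$four_group$test$p else NULL
  )
  jsonlite::write_json(report, .out_file(cfg, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  .write_manifest(cfg, seed)
  invisible(list(landscape = land, panels = panels, survival = surv,
                 report = report))
}

# manifest: config hash, package version, seed, timestamps, input checksums
.write_manifest <- function(cfg, seed) {
  cfg_json <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  tf <- tempfile(); writeLines(cfg_json, tf)
  inputs <- Filter(function(p) is.character(p) && file.exists(p),
                   cfg$paths[setdiff(names(cfg$paths), "out_dir")])
  manifest <- list(
    package = "emtscape",
    version = as.character(utils::packageVersion("emtscape")),
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config_md5 = unname(tools::md5sum(tf)),
    input_md5 = lapply(inputs, function(p) unname(tools::md5sum(p)))
  )
  unlink(tf)
  jsonlite::write_json(manifest, .out_file(cfg, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
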