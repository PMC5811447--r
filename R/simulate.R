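#' Configuration for the synthetic cohort generator
#'
#' The generator emulates the kind of z-scored gene x sample matrix the
#' pipeline consumes, with planted ground truth at every stage: a latent
#' per-sample EMT axis, immune metagene blocks coupled to it, per-sample
#' binary infiltration events, cytokine/checkpoint shifts, and
#' right-censored exponential survival.
#'
#' @param n_samples number of samples (>= 9 so tertiles are non-trivial).
#' @param seed integer seed; all draws flow from it.
#' @param emt_effect mean z-shift per unit latent EMT level on mesenchymal
#'   genes (epithelial genes get the opposite sign).
#' @param immune_coupling target coupling in `[-1, 1]` between the latent
#'   EMT level and anti-tumor metagene block means; negative values plant
#'   immune exclusion. Pro-tumor blocks (Treg, activated B cell, ...) get
#'   `+|immune_coupling|`.
#' @param cytokine_shift named per-gene z-shift per unit latent EMT level
#'   for cytokine/checkpoint genes; default [default_panel_shifts()].
#' @param n_cell_types number of immune metagene blocks (default 31).
#' @param genes_per_set genes per metagene block (default 20, disjoint).
#' @param noise_sd gene-level Gaussian noise standard deviation (z units).
#' @param base_infiltration_rate probability that a (sample, cell type)
#'   pair truly infiltrates, independent of the EMT axis.
#' @param infiltration_effect mean z-shift of a block's genes when its cell
#'   type truly infiltrates the sample.
#' @param survival list: `baseline_hazard` (events/day), `group_loghr`
#'   (named log-hazard ratios for latent groups high/mid/low),
#'   `censoring_rate` in `[0, 1)`.
#' @return A validated `SimulationConfig` list.
#' @export
simulation_config <- function(n_samples = 300L, seed,
                              emt_effect = 1,
                              immune_coupling = -0.6,
                              cytokine_shift = default_panel_shifts(),
                              n_cell_types = 31L,
                              genes_per_set = 20L,
                              noise_sd = 1,
                              base_infiltration_rate = 0.25,
                              infiltration_effect = 2,
                              survival = list(baseline_hazard = 1 / 1000,
                                              group_loghr = c(high = 0, mid = 0, low = 0),
                                              censoring_rate = 0.4)) {
  if (missing(seed)) stop_validation("simulation_config requires a seed")
  if (n_samples < 9L) stop_validation("n_samples must be >= 9")
  if (noise_sd <= 0) stop_validation("noise_sd must be > 0")
  if (abs(immune_coupling) > 1) stop_validation("immune_coupling must be in [-1, 1]")
  if (n_cell_types < 1L || genes_per_set < 2L)
    stop_validation("need >= 1 cell type with >= 2 genes per set")
  cr <- survival$censoring_rate %||% 0
  if (cr < 0 || cr >= 1) stop_validation("censoring_rate must be in [0, 1)")
  if (is.null(survival$baseline_hazard) || survival$baseline_hazard <= 0)
    stop_validation("baseline_hazard must be > 0")
  loghr <- survival$group_loghr %||% c(high = 0, mid = 0, low = 0)
  if (!all(c("high", "mid", "low") %in% names(loghr)))
    stop_validation("group_loghr must name high, mid, low")
  survival$group_loghr <- loghr
  survival$censoring_rate <- cr
  structure(list(n_samples = as.integer(n_samples), seed = as.integer(seed),
                 emt_effect = emt_effect, immune_coupling = immune_coupling,
                 cytokine_shift = cytokine_shift,
                 n_cell_types = as.integer(n_cell_types),
                 genes_per_set = as.integer(genes_per_set),
                 noise_sd = noise_sd,
                 base_infiltration_rate = base_infiltration_rate,
                 infiltration_effect = infiltration_effect,
                 survival = survival),
            class = "SimulationConfig")
}

#' Default planted shifts for cytokine and checkpoint genes
#'
#' A moderate positive coupling (0.5 z per unit latent EMT) for every
#' cytokine and checkpoint gene except CD274, which is left flat — the
#' constellation the method is meant to resolve: broadly up-shifted
#' cytokines/checkpoints in mesenchymal tumors with a null PD-L1.
#'
#' @return Named numeric vector of per-gene shifts.
#' @export
default_panel_shifts <- function() {
  g <- union(cytokine_panel(), checkpoint_panel())
  shifts <- stats::setNames(rep(0.5, length(g)), g)
  shifts["CD274"] <- 0
  shifts
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws a latent EMT level `e_s ~ N(0, 1)` per sample, then builds gene
#' rows: mesenchymal signature genes at `+emt_effect * e_s`, epithelial at
#' `-emt_effect * e_s`; each immune metagene block at
#' `coupling_c * e_s + infiltration_effect * I_sc` where `I_sc` is the
#' planted binary infiltration event; cytokine/checkpoint genes at their
#' configured per-gene shift times `e_s`; CD8 marker genes (CD8A, CD8B,
#' PRF1) track the activated-CD8 block. Independent Gaussian noise
#' (`noise_sd`) is added to every cell. Survival times are exponential with
#' group log-hazards on the latent tertiles and independent exponential
#' censoring calibrated to the configured censoring rate.
#'
#' @param cfg a [simulation_config()].
#' @return list with `expression` ([expression_matrix()], z-scored),
#'   `clinical` (data.frame), `cell_sets` ([gene_set_collection()]),
#'   `truth` (latent levels, true groups, infiltration matrix, shifts,
#'   survival parameters) and `config`.
#' @export
generate_cohort <- function(cfg) {
  if (!inherits(cfg, "SimulationConfig"))
    stop_validation("`cfg` must come from simulation_config()")
  withr_seed(cfg$seed, .generate_cohort_impl(cfg))
}

.generate_cohort_impl <- function(cfg) {
  n <- cfg$n_samples
  samples <- sprintf("S%04d", seq_len(n))
  e <- stats::rnorm(n)
  names(e) <- samples

  sig <- emt_signature()
  types <- .cell_type_table(cfg$n_cell_types)
  coupling <- c(anti_tumor = cfg$immune_coupling,
                pro_tumor = abs(cfg$immune_coupling),
                neutral = 0)[types$role]
  names(coupling) <- types$cell_type

  block_genes <- lapply(types$cell_type, function(ct)
    sprintf("%s_G%02d", toupper(ct), seq_len(cfg$genes_per_set)))
  names(block_genes) <- types$cell_type

  shifts <- cfg$cytokine_shift
  panel_genes <- names(shifts)
  cd8_extra <- setdiff(cd8_panel(), panel_genes)  # CD8A, CD8B, PRF1

  genes <- c(sig$epithelial, sig$mesenchymal, unlist(block_genes),
             panel_genes, cd8_extra)
  G <- length(genes)
  mu <- matrix(0, G, n, dimnames = list(genes, samples))

  mu[sig$epithelial, ] <- matrix(-cfg$emt_effect * e,
                                 length(sig$epithelial), n, byrow = TRUE)
  mu[sig$mesenchymal, ] <- matrix(cfg$emt_effect * e,
                                  length(sig$mesenchymal), n, byrow = TRUE)

  infil <- matrix(stats::runif(n * nrow(types)) < cfg$base_infiltration_rate,
                  n, nrow(types), dimnames = list(samples, types$cell_type))
  for (ct in types$cell_type) {
    block_mean <- coupling[ct] * e + cfg$infiltration_effect * infil[, ct]
    mu[block_genes[[ct]], ] <- matrix(block_mean, cfg$genes_per_set, n,
                                      byrow = TRUE)
  }
  mu[panel_genes, ] <- outer(shifts, e)
  cd8_ct <- "Activated_CD8_T_cell"
  if (length(cd8_extra) && cd8_ct %in% types$cell_type) {
    cd8_mean <- coupling[cd8_ct] * e + cfg$infiltration_effect * infil[, cd8_ct]
    mu[cd8_extra, ] <- matrix(cd8_mean, length(cd8_extra), n, byrow = TRUE)
  }

  z <- mu + matrix(stats::rnorm(G * n, sd = cfg$noise_sd), G, n)
  expr <- expression_matrix(z, genes, samples, is_zscored = TRUE)

  true_groups <- stratify_tertiles(
    data.frame(sample_id = samples, score = as.numeric(e),
               stringsAsFactors = FALSE), basis = "latent_emt")

  sv <- cfg$survival
  loghr <- sv$group_loghr[true_groups$label]
  hazard <- sv$baseline_hazard * exp(loghr)
  t_event <- stats::rexp(n, rate = hazard)
  if (sv$censoring_rate > 0) {
    rate_c <- sv$baseline_hazard * sv$censoring_rate / (1 - sv$censoring_rate)
    t_cens <- stats::rexp(n, rate = rate_c)
  } else {
    t_cens <- rep(Inf, n)
  }
  clinical <- data.frame(sample_id = samples,
                         os_time = pmin(t_event, t_cens),
                         os_event = as.integer(t_event <= t_cens),
                         stringsAsFactors = FALSE)

  list(
    expression = expr,
    clinical = clinical,
    cell_sets = gene_set_collection(block_genes,
                                    descriptions = types$role),
    truth = list(latent_emt = e, true_groups = true_groups,
                 infiltration = infil, coupling = coupling,
                 panel_shifts = shifts, survival = sv),
    config = cfg
  )
}

# first n_cell_types rows of the default table; extra types are neutral
.cell_type_table <- function(n_cell_types) {
  tab <- immune_cell_types()
  if (n_cell_types <= nrow(tab)) return(tab[seq_len(n_cell_types), , drop = FALSE])
  extra <- data.frame(
    cell_type = sprintf("Neutral_cell_type_%02d", seq_len(n_cell_types - nrow(tab))),
    role = "neutral", stringsAsFactors = FALSE)
  rbind(tab, extra)
}

#' Recovery metrics of pipeline outputs against planted truth
#'
#' @param truth the `truth` element of [generate_cohort()] output.
#' @param emt_scores data.frame from [emt_score()] on the same cohort.
#' @param calls optional output of [call_infiltration()].
#' @param panel optional output of [panel_compare()].
#' @return list with `emt_spearman` (rank correlation between latent EMT
#'   level and computed score), and when available `call_sensitivity`,
#'   `call_specificity` (against the planted infiltration matrix) and
#'   `shift_sign_agreement` (fraction of truly shifted panel genes whose
#'   measured mean difference has the planted sign).
#' @export
truth_report <- function(truth, emt_scores, calls = NULL, panel = NULL) {
  if (!setequal(emt_scores$sample_id, names(truth$latent_emt)))
    stop_validation("sample sets of truth and scores differ")
  e <- truth$latent_emt[emt_scores$sample_id]
  out <- list(emt_spearman = stats::cor(e, emt_scores$score,
                                        method = "spearman"))
  if (!is.null(calls)) {
    truth_flat <- truth$infiltration[cbind(
      match(calls$sample_id, rownames(truth$infiltration)),
      match(calls$cell_type, colnames(truth$infiltration)))]
    if (anyNA(truth_flat))
      stop_validation("calls refer to samples or cell types absent from truth")
    out$call_sensitivity <- mean(calls$call[truth_flat])
    out$call_specificity <- mean(!calls$call[!truth_flat])
  }
  if (!is.null(panel)) {
    planted <- truth$panel_shifts[panel$gene]
    nz <- !is.na(planted) & planted != 0
    if (any(nz))
      out$shift_sign_agreement <- mean(sign(panel$mean_diff[nz]) == sign(planted[nz]))
  }
  out
}
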