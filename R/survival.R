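#' Kaplan-Meier curve for one group
#'
#' Product-limit estimator via [survival::survfit()]. Censored observations
#' reduce the at-risk count without a step; ties between events and
#' censorings at the same time follow the standard convention (censoring
#' after events).
#'
#' @param time non-negative follow-up times (days).
#' @param event event indicators (1 = death observed, 0 = censored).
#' @return A `KMCurve` data.frame: `time`, `n_risk`, `n_event`, `survival`.
#' @export
km_estimate <- function(time, event) {
  if (!length(time)) stop_validation("km_estimate needs >= 1 record")
  if (any(is.na(time)) || any(time < 0))
    stop_validation("times must be non-negative and non-missing")
  if (!all(event %in% c(0, 1))) stop_validation("event must be 0 or 1")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, survival = fit$surv)
  class(out) <- c("KMCurve", "data.frame")
  out
}

#' @export
plot.KMCurve <- function(x, ..., xlab = "Time (days)", ylab = "Survival") {
  graphics::plot(c(0, x$time), c(1, x$survival), type = "s",
                 ylim = c(0, 1), xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' k-sample log-rank test
#'
#' Standard log-rank chi-square with k - 1 degrees of freedom via
#' [survival::survdiff()].
#'
#' @param time,event as in [km_estimate()].
#' @param group group labels (k >= 2 non-empty groups).
#' @return list with `chi2`, `df`, `p`, `n` (per-group sizes).
#' @export
logrank_test <- function(time, event, group) {
  group <- as.character(group)
  if (any(is.na(group)) || any(!nzchar(group)))
    stop_validation("every record needs a non-empty group label")
  sizes <- table(group)
  if (length(sizes) < 2L)
    stop_degenerate("log-rank test needs >= 2 non-empty groups")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- length(sizes) - 1L
  chi2 <- unname(sd$chisq)
  list(chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df = df, lower.tail = FALSE),
       n = as.integer(sizes))
}

#' Survival contrasts by EMT group and activated-CD8 infiltration
#'
#' Drops the mid tertile, then runs (i) a two-group log-rank test of the
#' mesenchymal (`high`) versus epithelial (`low`) EMT groups and (ii) a
#' four-group test crossing EMT group with the per-sample activated-CD8
#' T-cell infiltration call. Samples missing survival data are dropped
#' before grouping; empty subgroups are dropped with a warning and the
#' degrees of freedom adjusted.
#'
#' @param clinical data.frame from [read_clinical()].
#' @param emt_groups tertile assignment from [stratify_tertiles()].
#' @param calls output of [call_infiltration()] (used for the 4-group
#'   analysis; `NULL` skips it).
#' @param cd8_cell_type name of the activated CD8 T-cell signature in
#'   `calls` (default `"Activated_CD8_T_cell"`).
#' @return list with elements `two_group` and (when calls are given)
#'   `four_group`, each holding the [logrank_test()] result, per-group KM
#'   curves, and group sizes; plus `n_used`.
#' @export
emt_survival_analysis <- function(clinical, emt_groups, calls = NULL,
                                  cd8_cell_type = "Activated_CD8_T_cell") {
  grp <- emt_groups[emt_groups$label %in% c("high", "low"), , drop = FALSE]
  dat <- merge(clinical, grp, by = "sample_id")
  if (!nrow(dat))
    stop_validation("no overlap between clinical table and EMT groups")
  dat$emt <- ifelse(dat$label == "high", "mesenchymal", "epithelial")

  two <- logrank_test(dat$os_time, dat$os_event, dat$emt)
  curves2 <- lapply(split(dat, dat$emt), function(d)
    km_estimate(d$os_time, d$os_event))
  out <- list(
    two_group = list(test = two, curves = curves2,
                     n = table(dat$emt)),
    n_used = nrow(dat)
  )

  if (!is.null(calls)) {
    cc <- calls[calls$cell_type == cd8_cell_type, , drop = FALSE]
    if (!nrow(cc))
      stop_validation(sprintf("cell type %s absent from calls", cd8_cell_type))
    dat$cd8 <- cc$call[match(dat$sample_id, cc$sample_id)]
    dat4 <- dat[!is.na(dat$cd8), , drop = FALSE]
    dat4$subgroup <- paste0(dat4$emt, "/CD8_",
                            ifelse(dat4$cd8, "present", "absent"))
    sizes <- table(dat4$subgroup)
    if (any(sizes == 0L) || length(sizes) < 4L)
      warning("empty EMT x CD8 subgroup(s) dropped; degrees of freedom adjusted")
    if (length(unique(dat4$subgroup)) < 2L) {
      warning("fewer than 2 non-empty subgroups; four-group test skipped")
      out$four_group <- list(test = NULL, n = sizes)
    } else {
      four <- logrank_test(dat4$os_time, dat4$os_event, dat4$subgroup)
      curves4 <- lapply(split(dat4, dat4$subgroup), function(d)
        km_estimate(d$os_time, d$os_event))
      out$four_group <- list(test = four, curves = curves4, n = sizes)
    }
  }
  out
}
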