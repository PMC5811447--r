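# Independent oracles used across test files. These deliberately take the
# slow, literal route so they stay independent of the package internals.

# exhaustive running-sum evaluation of the weighted KS enrichment score:
# visit every rank position, track the extreme deviations of the sum
brute_force_es <- function(weights, hit_positions, n) {
  k <- length(hit_positions)
  if (k >= n) return(1)
  w <- weights[hit_positions]
  if (sum(w) <= 0) w <- rep(1, k)
  W <- sum(w)
  run <- 0
  hi <- 0
  lo <- 0
  for (i in seq_len(n)) {
    j <- match(i, hit_positions)
    run <- if (!is.na(j)) run + w[j] / W else run - 1 / (n - k)
    hi <- max(hi, run)
    lo <- min(lo, run)
  }
  # same tie rule as the package: a tied extreme resolves positive
  if (hi + lo >= -1e-12) hi else lo
}

# literal product-limit estimator: S(t) = prod over event times <= t of
# (1 - d_i / n_i), censorings at a tied time counted as still at risk
brute_force_km <- function(time, event) {
  times <- sort(unique(time[event == 1]))
  surv <- numeric(length(times))
  s <- 1
  for (i in seq_along(times)) {
    t <- times[i]
    n_risk <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / n_risk)
    surv[i] <- s
  }
  data.frame(time = times, survival = surv)
}

# k-sample log-rank chi-square from first principles (sum over event times
# of observed minus expected, with the hypergeometric variance), for k = 2
logrank_chi2_2group <- function(time, event, group) {
  g <- sort(unique(group))
  stopifnot(length(g) == 2)
  times <- sort(unique(time[event == 1]))
  O <- 0; E <- 0; V <- 0
  for (t in times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g[1])
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g[1])
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# small convenience: a z-scored ExpressionMatrix from a plain matrix
zmat <- function(values, genes = NULL, samples = NULL) {
  genes <- genes %||% sprintf("G%03d", seq_len(nrow(values)))
  samples <- samples %||% sprintf("s%03d", seq_len(ncol(values)))
  expression_matrix(matrix(values, nrow = length(genes),
                           dimnames = list(genes, samples)),
                    is_zscored = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
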