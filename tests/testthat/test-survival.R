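test_that("Kaplan-Meier estimate matches the product-limit formula", {
  flat <- km_estimate(c(5, 10, 15), c(0, 0, 0))
  expect_true(all(flat$survival == 1) || nrow(flat) == 0)

  two <- km_estimate(c(1, 2), c(1, 1))
  expect_equal(two$survival, c(0.5, 0))

  set.seed(13)
  time <- round(rexp(50, 0.01)) + 1
  event <- rbinom(50, 1, 0.7)
  got <- km_estimate(time, event)
  want <- brute_force_km(time, event)
  ev <- got[got$n_event > 0, ]
  expect_equal(ev$time, want$time)
  expect_equal(ev$survival, want$survival, tolerance = 1e-12)

  expect_error(km_estimate(c(-1, 2), c(1, 1)),
               class = "emtscape_validation_error")
  expect_error(km_estimate(numeric(0), numeric(0)),
               class = "emtscape_validation_error")
})

test_that("KM curve ignores record order and trailing censored observations", {
  set.seed(19)
  time <- round(rexp(40, 0.02)) + 1
  event <- rbinom(40, 1, 0.6)
  a <- km_estimate(time, event)
  perm <- sample(40)
  b <- km_estimate(time[perm], event[perm])
  expect_equal(a, b)
  # a censoring already past the last event can be delayed arbitrarily
  # without touching any risk set, so the curve is unchanged
  time2 <- c(time, max(time) + 100)
  event2 <- c(event, 0)
  d1 <- km_estimate(time2, event2)
  time3 <- time2; time3[41] <- time3[41] + 5000
  d2 <- km_estimate(time3, event2)
  expect_equal(d1$survival, d2$survival[seq_len(nrow(d1))])
  expect_equal(sum(d1$n_event), sum(d2$n_event))
})

test_that("log-rank test matches first-principles computation and symmetries", {
  time <- c(3, 5, 8, 10, 2, 6, 9, 12)
  event <- c(1, 1, 0, 1, 1, 1, 1, 0)
  group <- rep(c("a", "b"), each = 4)
  got <- logrank_test(time, event, group)
  expect_equal(got$df, 1)
  expect_equal(got$chi2, logrank_chi2_2group(time, event, group),
               tolerance = 1e-10)
  expect_equal(got$p, pchisq(got$chi2, 1, lower.tail = FALSE),
               tolerance = 1e-12)

  relabel <- logrank_test(time, event, c("b", "a")[match(group, c("a", "b"))])
  expect_equal(relabel$chi2, got$chi2)

  dup <- logrank_test(rep(time[1:4], 2), rep(event[1:4], 2),
                      rep(c("a", "b"), each = 4))
  expect_equal(dup$chi2, 0, tolerance = 1e-10)
  expect_equal(dup$p, 1, tolerance = 1e-10)

  expect_error(logrank_test(time, event, rep("a", 8)),
               class = "emtscape_degenerate_error")
})

test_that("log-rank detects a planted hazard ratio and its power is monotone", {
  set.seed(29)
  t1 <- rexp(200, 1); t2 <- rexp(200, 3)
  sep <- logrank_test(c(t1, t2), rep(1, 400), rep(c("a", "b"), each = 200))
  expect_lt(sep$p, 0.001)

  power_at <- function(hr, n_sim = 60, n = 120) {
    sig <- 0L
    for (i in seq_len(n_sim)) {
      ta <- rexp(n, 1); tb <- rexp(n, hr)
      cens <- rexp(2 * n, 0.3)
      time <- pmin(c(ta, tb), cens)
      event <- as.integer(c(ta, tb) <= cens)
      p <- logrank_test(time, event, rep(c("a", "b"), each = n))$p
      sig <- sig + (p < 0.05)
    }
    sig / n_sim
  }
  set.seed(101)
  pw <- vapply(c(1, 1.5, 2, 3), power_at, numeric(1))
  expect_true(all(diff(pw) >= -0.05))
  expect_lt(pw[1], 0.2)
  expect_gt(pw[4], 0.9)
})

test_that("EMT survival analysis builds the 2- and 4-group contrasts", {
  sim <- generate_cohort(simulation_config(
    n_samples = 240, seed = 83, n_cell_types = 8,
    survival = list(baseline_hazard = 1 / 500,
                    group_loghr = c(high = log(2), mid = 0, low = 0),
                    censoring_rate = 0.3)))
  emt <- emt_score(sim$expression)
  groups <- stratify_tertiles(emt)
  enr <- sample_enrichment(sim$expression, sim$cell_sets,
                           n_perm = 200, seed = 84)
  calls <- call_infiltration(enr)
  res <- emt_survival_analysis(sim$clinical, groups, calls = calls)
  # planted two-fold mesenchymal hazard: clearly significant at this n
  expect_lt(res$two_group$test$p, 0.01)
  expect_equal(res$two_group$test$df, 1)
  expect_equal(res$n_used, 160)
  expect_equal(sum(res$four_group$n), 160)
  expect_equal(res$four_group$test$df, length(res$four_group$n) - 1)
  expect_true(all(vapply(res$two_group$curves, function(cv)
    all(diff(cv$survival) <= 1e-12), logical(1))))
})

test_that("degenerate subgroup structure is handled with a warning", {
  clinical <- data.frame(sample_id = sprintf("s%d", 1:40),
                         os_time = rexp(40, 0.01), os_event = 1)
  groups <- data.frame(sample_id = sprintf("s%d", 1:40),
                       label = rep(c("high", "low"), each = 20), basis = "x")
  calls <- data.frame(sample_id = sprintf("s%d", 1:40),
                      cell_type = "Activated_CD8_T_cell",
                      es = 0.5, p_emp = 0.01, q = 0.02, call = TRUE)
  expect_warning(res <- emt_survival_analysis(clinical, groups, calls = calls),
                 "subgroup")
  expect_equal(res$four_group$test$df, 1)
})
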