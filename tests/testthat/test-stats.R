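test_that("chi-square on 2x2 tables matches the closed form", {
  even <- chi_square_2x2(matrix(c(10, 10, 10, 10), 2))
  expect_equal(even$chi2, 0)
  expect_equal(even$p, 1)

  # sum((O - E)^2 / E) with all expected counts 20
  skew <- chi_square_2x2(matrix(c(30, 10, 10, 30), 2))
  expect_equal(skew$chi2, 20, tolerance = 1e-10)
  expect_equal(skew$df, 1)

  swapped <- chi_square_2x2(matrix(c(10, 30, 30, 10), 2))
  expect_equal(swapped$chi2, skew$chi2)
  expect_equal(swapped$p, skew$p)

  expect_error(chi_square_2x2(matrix(c(0, 0, 5, 5), 2)),
               class = "emtscape_degenerate_error")
  expect_error(chi_square_2x2(matrix(1, 3, 3)),
               class = "emtscape_validation_error")
})

test_that("chi-square equals sum((O-E)^2/E) on random tables", {
  set.seed(17)
  for (i in 1:200) {
    tab <- matrix(rpois(4, 20) + 1, 2)
    got <- chi_square_2x2(tab)$chi2
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    expect_equal(got, sum((tab - E)^2 / E), tolerance = 1e-10)
  }
})

test_that("fold change uses the Haldane-Anscombe pseudocount", {
  expect_equal(fold_change(10, 100, 10, 100), 1)
  fc <- fold_change(0, 100, 50, 100)
  expect_lt(fc, 0.02)
  expect_gt(fc, 0)
  # doubling counts and totals moves the value only through the pseudocount
  expect_equal(fold_change(20, 200, 100, 200),
               fold_change(10, 100, 50, 100), tolerance = 0.05)
})

test_that("Welch's t matches the textbook formula and its symmetries", {
  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  x <- c(1, 2, 3); y <- c(2, 3, 4)
  got <- welch_t(x, y)
  se2 <- var(x) / 3 + var(y) / 3
  t_hand <- (mean(x) - mean(y)) / sqrt(se2)
  df_hand <- se2^2 / ((var(x) / 3)^2 / 2 + (var(y) / 3)^2 / 2)
  expect_equal(got$t, t_hand, tolerance = 1e-10)
  expect_equal(got$df, df_hand, tolerance = 1e-10)
  expect_equal(got$p, 2 * pt(-abs(t_hand), df_hand), tolerance = 1e-10)
  expect_lte(got$df, 4 + 1e-12)

  rev <- welch_t(y, x)
  expect_equal(rev$t, -got$t)
  expect_equal(rev$p, got$p)

  const <- welch_t(c(2, 2, 2), c(2, 2))
  expect_equal(const$t, 0)
  expect_equal(const$p, 1)
  expect_error(welch_t(1, c(1, 2)), class = "emtscape_degenerate_error")
  expect_error(welch_t(c(1, 1), c(2, 2)), class = "emtscape_degenerate_error")
})

test_that("simple regression matches the closed-form sums", {
  x <- c(0, 1, 2, 3)
  fit <- suppressWarnings(simple_linreg(x, 2 * x))  # lm flags the exact fit
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$r2, 1, tolerance = 1e-12)

  y <- c(1.1, 1.9, 3.2, 3.8)
  got <- simple_linreg(x, y)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  sxx <- sum((x - mean(x))^2)
  expect_equal(got$slope, sxy / sxx, tolerance = 1e-10)
  expect_equal(got$intercept, mean(y) - sxy / sxx * mean(x), tolerance = 1e-10)
  expect_equal(got$r2, cor(x, y)^2, tolerance = 1e-10)

  expect_error(simple_linreg(rep(1, 5), rnorm(5)),
               class = "emtscape_degenerate_error")
})

test_that("regression recovers a planted slope within 3 standard errors", {
  set.seed(23)
  hits <- 0L
  n_sim <- 200L
  for (i in seq_len(n_sim)) {
    x <- rnorm(300)
    y <- 0.4 * x + rnorm(300)
    fit <- lm(y ~ x)
    se <- summary(fit)$coefficients[2, 2]
    hits <- hits + (abs(coef(fit)[2] - 0.4) <= 3 * se)
  }
  expect_gte(hits, 195L)
})

test_that("panel contrasts flag only the planted genes and agree with welch_t", {
  sim <- generate_cohort(simulation_config(
    n_samples = 240, seed = 61, n_cell_types = 3,
    cytokine_shift = c(IL10 = 1, TGFB1 = 1, IL2 = 0, TNF = 0, CD274 = 0)))
  emt <- emt_score(sim$expression)
  groups <- stratify_tertiles(emt)
  panel <- panel_compare(sim$expression, groups,
                         c("IL10", "TGFB1", "IL2", "TNF", "CD274"),
                         emt_scores = emt)
  flagged <- panel$gene[panel$p_bh < 0.05 & panel$mean_diff > 0]
  expect_setequal(flagged, c("IL10", "TGFB1"))
  expect_gt(min(panel$r2[panel$gene %in% c("IL10", "TGFB1")]),
            max(panel$r2[panel$gene %in% c("IL2", "TNF", "CD274")]))

  one <- panel_compare(sim$expression, groups, "IL10")
  hi <- groups$sample_id[groups$label == "high"]
  lo <- groups$sample_id[groups$label == "low"]
  direct <- welch_t(as.numeric(sim$expression["IL10", hi]),
                    as.numeric(sim$expression["IL10", lo]))
  expect_equal(one$t, direct$t)
  expect_equal(one$p, direct$p)

  expect_error(panel_compare(sim$expression, groups, character(0)),
               class = "emtscape_validation_error")
  expect_warning(panel_compare(sim$expression, groups, c("IL10", "NOPE")),
                 "NOPE")
})

test_that("statistics are invariant to sample ordering", {
  set.seed(9)
  x <- rnorm(30); y <- rnorm(30)
  p1 <- welch_t(x, y); p2 <- welch_t(sample(x), sample(y))
  expect_equal(p1$t, p2$t)
  xr <- rnorm(30); perm <- sample(30)
  f1 <- simple_linreg(xr, y); f2 <- simple_linreg(xr[perm], y[perm])
  expect_equal(f1$slope, f2$slope)
  expect_equal(f1$p_slope, f2$p_slope)
})
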