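test_that("per-sample ranking sorts by z descending with symbol tie-break", {
  m <- zmat(matrix(c(2, -1, 0), 3, 1), genes = c("A", "B", "C"),
            samples = "s1")
  r <- rank_genes(m, "s1")
  expect_identical(r$gene, c("A", "C", "B"))

  mt <- zmat(matrix(c(1, 1), 2, 1), genes = c("B", "A"), samples = "s1")
  expect_identical(rank_genes(mt, "s1")$gene, c("A", "B"))
  expect_error(rank_genes(mt, "nope"), class = "emtscape_validation_error")

  set.seed(12)
  m2 <- zmat(matrix(rnorm(100), 100, 1))
  r2 <- rank_genes(m2, colnames(m2))
  expect_identical(r2$gene, rownames(m2)[order(-as.numeric(m2[, 1]),
                                               rownames(m2))])
  expect_equal(r2$weight, abs(r2$z))
})

test_that("enrichment score hits its analytic extremes", {
  # set occupying the very top of the ranking: running sum peaks at 1
  ranked <- data.frame(gene = sprintf("G%02d", 1:10), weight = rep(1, 10))
  expect_equal(enrichment_score(ranked, c("G01", "G02")), 1)
  # set at the very bottom: deepest point before any hit is negative
  expect_lt(enrichment_score(ranked, c("G09", "G10")), 0)
  expect_error(enrichment_score(ranked, c("X1", "X2")),
               class = "emtscape_degenerate_error")
})

test_that("enrichment score equals exhaustive running-sum evaluation", {
  set.seed(99)
  for (i in 1:60) {
    n <- sample(3:12, 1)
    k <- sample(1:(n - 1), 1)
    w <- abs(rnorm(n))^sample(c(0, 1), 1)
    ranked <- data.frame(gene = sprintf("G%02d", 1:n), weight = w)
    set_genes <- sprintf("G%02d", sample(n, k))
    pos <- sort(match(set_genes, ranked$gene))
    expect_equal(enrichment_score(ranked, set_genes),
                 brute_force_es(w, pos, n), tolerance = 1e-12)
  }
})

test_that("enrichment score agrees with fgsea's GSEA statistic", {
  set.seed(35)
  z <- rnorm(300)
  names(z) <- sprintf("G%03d", seq_along(z))
  m <- zmat(matrix(z, 300, 1), genes = names(z))
  for (alpha in c(0, 1)) {
    ranked <- rank_genes(m, colnames(m), alpha = alpha)
    stats_sorted <- sort(z, decreasing = TRUE)
    for (i in 1:10) {
      sel <- sample(names(z), 12)
      expect_equal(
        enrichment_score(ranked, sel),
        fgsea::calcGseaStat(stats_sorted,
                            selectedStats = match(sel, names(stats_sorted)),
                            gseaParam = alpha),
        tolerance = 1e-9)
    }
  }
})

test_that("rank-only score is invariant under monotone transformations of z", {
  set.seed(4)
  z <- rnorm(30)
  m1 <- zmat(matrix(z, 30, 1))
  m2 <- zmat(matrix(exp(z) + 3, 30, 1), genes = rownames(m1))
  set_genes <- rownames(m1)[sample(30, 6)]
  es1 <- enrichment_score(rank_genes(m1, colnames(m1), alpha = 0), set_genes)
  es2 <- enrichment_score(rank_genes(m2, colnames(m2), alpha = 0), set_genes)
  expect_equal(es1, es2)
})

test_that("permutation p-values are seeded, floored and contract-checked", {
  set.seed(2)
  z <- c(rep(5, 4), rnorm(96))
  m <- zmat(matrix(z, 100, 1))
  top4 <- rownames(m)[1:4]
  ranked <- rank_genes(m, colnames(m))
  r1 <- permutation_pvalue(ranked, top4, n_perm = 999, seed = 10)
  # observed score beats every permutation: p hits its floor 1/(n_perm + 1)
  expect_equal(r1$p_emp, 1 / 1000)
  r2 <- permutation_pvalue(ranked, top4, n_perm = 999, seed = 10)
  expect_identical(r1, r2)
  expect_error(permutation_pvalue(ranked, top4, n_perm = 99, seed = 1),
               class = "emtscape_validation_error")
  expect_error(permutation_pvalue(ranked, top4, n_perm = 500),
               class = "emtscape_validation_error")
})

test_that("null permutation p-values are uniform", {
  # pure-noise universe: score random sets, p must be Uniform(0, 1]
  set.seed(31)
  n_genes <- 200L
  m <- zmat(matrix(rnorm(n_genes * 40), n_genes, 40))
  sets <- gene_set_collection(setNames(
    lapply(1:10, function(i) rownames(m)[sample(n_genes, 15)]),
    sprintf("NULLSET%02d", 1:10)))
  enr <- sample_enrichment(m, sets, n_perm = 500, seed = 77)
  ks <- suppressWarnings(ks.test(enr$p_emp, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("BH q-values and infiltration calls match the hand-worked example", {
  res <- data.frame(sample_id = "s1",
                    cell_type = sprintf("CT%d", 1:5),
                    es = c(0.5, 0.4, -0.2, 0.3, 0.1),
                    p_emp = c(0.01, 0.02, 0.03, 0.5, 0.9))
  calls <- call_infiltration(res, q_threshold = 0.10)
  expect_equal(calls$q, c(0.05, 0.05, 0.05, 0.625, 0.9))
  # CT3 has q <= 0.10 but a negative score, so it is not called
  expect_identical(calls$call, c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_true(all(calls$call == (calls$es > 0 & calls$q <= 0.10)))

  res$p_emp <- rep(1, 5)
  expect_false(any(call_infiltration(res)$call))

  # q_threshold = 1 calls every positive-score set
  res$p_emp <- runif(5)
  all_called <- call_infiltration(res, q_threshold = 1)
  expect_identical(all_called$call, all_called$es > 0)
})

test_that("call_infiltration validates its input shape", {
  res <- data.frame(sample_id = c("s1", "s1", "s2"),
                    cell_type = c("A", "B", "A"),
                    es = 0.1, p_emp = 0.5)
  expect_error(call_infiltration(res), class = "emtscape_validation_error")
})

test_that("enrichment calls are bit-reproducible under a fixed seed", {
  sim <- generate_cohort(simulation_config(n_samples = 12, seed = 5,
                                           n_cell_types = 4))
  e1 <- sample_enrichment(sim$expression, sim$cell_sets, n_perm = 150, seed = 9)
  e2 <- sample_enrichment(sim$expression, sim$cell_sets, n_perm = 150, seed = 9)
  expect_identical(e1, e2)
  expect_true(all(abs(e1$es) <= 1))
})

test_that("landscape on identical groups gives fold change 1 and p = 1", {
  calls <- data.frame(
    sample_id = rep(sprintf("s%02d", 1:20), each = 2),
    cell_type = rep(c("A", "B"), 20),
    es = 0.4, p_emp = 0.01, q = 0.02)
  # cell type A called for the first ten samples (both groups equally),
  # cell type B never called anywhere
  calls$call <- calls$cell_type == "A" &
    calls$sample_id %in% sprintf("s%02d", 1:10)
  groups <- data.frame(sample_id = sprintf("s%02d", 1:20),
                       label = rep(c("high", "low"), 10), basis = "x")
  expect_warning(land <- landscape(calls, groups), "margin")
  expect_equal(land$fold_change, c(1, 1))
  expect_equal(land$chi2[1], 0)
  expect_equal(land$p[1], 1)
  # cell type B: nobody called in either group -> degenerate margin flagged NA
  expect_true(is.na(land$p[2]))
})
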