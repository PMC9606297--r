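test_that("permutation mean test matches exhaustive enumeration", {
  set.seed(1)
  for (rep in 1:5) {
    x <- rnorm(3); y <- rnorm(3)
    res <- permutation_mean_difference_test(x, y)
    expect_identical(res$mode, "exact")
    expect_equal(res$p_value, oracle_perm_mean_p(x, y))
  }
  # identical values in both groups -> statistic 0, everything ties, p = 1
  res <- permutation_mean_difference_test(rep(2, 4), rep(2, 5))
  expect_equal(res$p_value, 1)
  expect_error(permutation_mean_difference_test(numeric(0), 1:3),
               "nonempty")
})

test_that("Monte-Carlo permutation p obeys the add-one rule", {
  x <- c(10, 11, 12, 13, 14, 15, 16, 17, 18, 19, 20)
  y <- c(0, 1, 2, 3, 4, 5, 6, 7, 8, 9, 21)
  res <- permutation_mean_difference_test(x, y, R = 1000, seed = 4,
                                          exact = FALSE)
  # p must be an achievable add-one value: (b+1)/(R+1)
  expect_true(res$p_value >= 1 / 1001)
  expect_equal((res$p_value * 1001) %% 1, 0, tolerance = 1e-9)
})

test_that("bootstrap correlation-set test behaves at its extremes", {
  v <- c(0.1, 0.3, 0.5, 0.7, 0.2, 0.6)
  res <- bootstrap_correlation_set_test(v, v, B = 4000, seed = 2)
  expect_equal(res$p_value, 0.5, tolerance = 0.05)
  # complete separation attains the add-one floor
  res2 <- bootstrap_correlation_set_test(rep(0.9, 6), rep(0.1, 6),
                                         B = 2000, seed = 2)
  expect_equal(res2$p_value, 1 / 2001)
  expect_warning(bootstrap_correlation_set_test(0.5, v, B = 1000),
                 "size 1")
  # self-consistency across B within Monte-Carlo error
  set.seed(7)
  w <- rnorm(8, 0.35, 0.2); cr <- rnorm(10, 0.25, 0.2)
  p1 <- bootstrap_correlation_set_test(w, cr, B = 2000, seed = 1)$p_value
  p2 <- bootstrap_correlation_set_test(w, cr, B = 20000, seed = 2)$p_value
  ci <- binom.test(round(p1 * 2001), 2001)$conf.int
  expect_gte(p2, ci[1] * 0.5)
  expect_lte(p2, min(1, ci[2] * 2))
})

test_that("Jonckheere-Terpstra is exact on small instances", {
  res <- jonckheere_terpstra(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(res$statistic, 12)
  expect_equal(res$p_value, 1 / 90)
  expect_identical(res$mode, "exact")
  # oracle agreement on random small instances
  set.seed(3)
  for (rep in 1:3) {
    g <- list(rnorm(3), rnorm(2), rnorm(2))
    expect_equal(jonckheere_terpstra(g)$p_value, oracle_jt_p(g))
  }
  # ties handled: all-identical groups give p = 1
  res_t <- jonckheere_terpstra(list(rep(1, 3), rep(1, 3)))
  expect_equal(res_t$p_value, 1)
  # reversed alternative on perfectly increasing data sits in the far tail
  rev <- jonckheere_terpstra(list(c(1, 2), c(3, 4), c(5, 6)),
                             alternative = "decreasing")
  expect_gte(rev$p_value, 1 - 2 / 90)
  expect_error(jonckheere_terpstra(list(1:3)), "2 nonempty")
})

test_that("JT permutation and normal modes approximate the exact p", {
  set.seed(5)
  g <- list(rnorm(5), rnorm(5) + 0.8, rnorm(5) + 1.6)
  pe <- jonckheere_terpstra(g, mode = "exact")$p_value
  pp <- jonckheere_terpstra(g, mode = "permutation", B = 4000,
                            seed = 1)$p_value
  pn <- jonckheere_terpstra(g, mode = "normal")$p_value
  expect_lt(abs(pp - pe), 0.02)
  expect_lt(abs(pn - pe), 0.02)
})

test_that("null simulation reproduces the spurious-correlation span", {
  ns <- null_simulation_study(reps = 300, seed = 2)
  expect_lt(ns$summary[["min_abs_r"]], 0.03)
  expect_gt(ns$summary[["max_abs_r"]], 0.5)
  expect_lt(ns$summary[["max_abs_r"]], 0.7)
  # consistency: with a large cohort the maximum correlation collapses
  big <- null_simulation_study(n_patients = 2000, reps = 100, seed = 2)
  expect_lt(big$summary[["max_abs_r"]], 0.1)
  expect_error(null_simulation_study(n_patients = 3), ">= 4")
})

test_that("KS uniformity sensitivity flags enriched p-value sets", {
  set.seed(6)
  universe <- runif(2000)
  # uniform observed set: KS p not extreme
  obs_u <- runif(14)
  r_u <- ks_uniformity_sensitivity(obs_u, universe, n_random_sets = 200,
                                   seed = 1)
  expect_gt(r_u$ks_p, 0.001)
  # all tiny p-values reject decisively
  r_t <- ks_uniformity_sensitivity(rep(0.001, 14), universe,
                                   n_random_sets = 50, seed = 1)
  expect_lt(r_t$ks_p, 1e-6)
  # Beta(0.3, 1) sets fall below the random-set 5th percentile mostly
  hits <- 0
  for (s in 1:30) {
    set.seed(s)
    obs <- rbeta(14, 0.3, 1)
    r <- ks_uniformity_sensitivity(obs, universe, n_random_sets = 200,
                                   seed = s)
    if (r$ks_p < quantile(r$random_ks_p, 0.05)) hits <- hits + 1
  }
  expect_gte(hits / 30, 0.8)
  expect_error(ks_uniformity_sensitivity(c(0.1, 0.5), universe), ">= 3")
  expect_error(ks_uniformity_sensitivity(c(0.1, 0.5, 0), universe),
               "\\(0, 1\\]")
})

test_that("GSEA running sum matches the brute-force oracle", {
  set.seed(8)
  for (rep in 1:10) {
    n <- sample(8:20, 1)
    ranking <- setNames(rnorm(n), paste0("g", seq_len(n)))
    set_size <- sample(2:(n - 2), 1)
    gs <- sample(names(ranking), set_size)
    res <- gsea_enrichment(ranking, gs, n_perm = 50, seed = rep)
    expect_equal(res$es, oracle_gsea_es(ranking, gs))
  }
  # top-of-ranking sets score positively, bottom sets negatively
  ranking <- setNames(seq(3, -3, length.out = 30), paste0("g", 1:30))
  expect_gt(gsea_enrichment(ranking, paste0("g", 1:6), n_perm = 50,
                            seed = 1)$es, 0)
  expect_lt(gsea_enrichment(ranking, paste0("g", 25:30), n_perm = 50,
                            seed = 1)$es, 0)
  expect_error(gsea_enrichment(ranking, paste0("g", 1:30)), "universe")
  expect_error(gsea_enrichment(ranking, "absent"), "intersect")
})

test_that("GSEA agrees with the fgsea reference statistic", {
  skip_if_not_installed("fgsea")
  set.seed(9)
  ranking <- setNames(sort(rnorm(40), decreasing = TRUE),
                      paste0("g", 1:40))
  gs <- sample(names(ranking), 8)
  ours <- gsea_enrichment(ranking, gs, n_perm = 100, seed = 1)$es
  ref <- fgsea::calcGseaStat(ranking, which(names(ranking) %in% gs),
                             gseaParam = 1, scoreType = "std")
  expect_equal(ours, ref, tolerance = 1e-9)
})

test_that("gene ranking applies the CPM filter and orders by t", {
  set.seed(10)
  counts <- matrix(rpois(50 * 8, 60), 50, 8,
                   dimnames = list(paste0("g", 1:50), paste0("s", 1:8)))
  # gene expressed only in the high group tops the ranking
  counts["g1", ] <- c(0, 0, 0, 0, 500, 520, 480, 510)
  # a gene with CPM below cutoff in > 90% of samples is removed
  counts["g2", ] <- 0L
  rk <- rank_genes_by_group_t(counts, group_low = 1:4, group_high = 5:8)
  expect_equal(rk$gene[1], "g1")
  expect_false("g2" %in% rk$gene)
  expect_true(all(diff(rk$t) <= 0))
  # permuted labels give roughly sign-symmetric statistics
  rk0 <- rank_genes_by_group_t(counts[-(1:2), ], group_low = c(1, 3, 5, 7),
                               group_high = c(2, 4, 6, 8))
  expect_lt(abs(mean(rk0$t > 0) - 0.5), 0.25)
})

test_that("CN-expression correlation separates planted driver genes", {
  hits <- 0
  for (seed in 1:30) {
    s <- simulate_expression_cn(n_genes = 120, n_samples = 60, seed = seed)
    cg <- cn_expression_correlation_groups(s$expr, s$cn, s$gene_groups)
    med <- tapply(cg$rho, s$gene_groups[names(cg$rho)], median,
                  na.rm = TRUE)
    top <- names(which.max(med))
    p <- cg$pairwise_p["driver_prevalent", "nondriver_nonprevalent"]
    if (top == "driver_prevalent" && p < 0.05) hits <- hits + 1
  }
  expect_gte(hits / 30, 0.9)
  # exact coupling gives rho 1; constant rows give NA
  expr <- rbind(a = c(1, 2, 3, 4), b = c(5, 5, 5, 5))
  cn <- rbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4))
  cg2 <- cn_expression_correlation_groups(expr, cn,
                                          c(a = "x", b = "y"))
  expect_equal(unname(cg2$rho["a"]), 1)
  expect_true(is.na(cg2$rho["b"]))
})

test_that("prediction ellipses have chi-square geometry", {
  q95 <- qchisq(0.95, 2)
  expect_equal(sqrt(q95), 2.4477, tolerance = 1e-4)
  # identity covariance -> circle of radius sqrt(q)
  set.seed(12)
  n <- 4000
  x <- rnorm(n); y <- rnorm(n)
  e <- prediction_ellipse(x, y)
  expect_equal(unname(e$radii), rep(sqrt(q95), 2), tolerance = 0.08)
  # rho = 0.99 -> axis ratio sqrt(1.99 / 0.01)
  S <- matrix(c(1, 0.99, 0.99, 1), 2)
  L <- chol(S)
  xy <- cbind(x, y) %*% L
  e2 <- prediction_ellipse(xy[, 1], xy[, 2])
  expect_equal(e2$radii[1] / e2$radii[2], sqrt(1.99 / 0.01),
               tolerance = 0.15)
  # rotating the data rotates the ellipse identically
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  xr <- cbind(x, 0.25 * y) %*% t(R)
  e3 <- prediction_ellipse(cbind(x, 0.25 * y)[, 1],
                           cbind(x, 0.25 * y)[, 2])
  e4 <- prediction_ellipse(xr[, 1], xr[, 2])
  ang_diff <- (e4$angle - e3$angle) %% pi
  expect_equal(min(ang_diff, pi - ang_diff), th %% pi, tolerance = 0.05)
  expect_equal(e4$radii, e3$radii, tolerance = 1e-6)
  # degenerate covariance flagged
  expect_warning(prediction_ellipse(1:5, 2 * (1:5)), "singular")
})

test_that("ordered association computes the linear-by-linear statistic", {
  tab <- matrix(c(10, 0, 0, 10), 2, 2)
  res <- ordered_cn_association(tab)
  expect_equal(res$ordered_statistic, 19)  # (N - 1) r^2 with r = 1
  expect_lt(res$ordered_p, 2e-5)
  # zero margins dropped with a warning
  tab3 <- rbind(c(5, 1, 0), c(2, 6, 0), c(0, 0, 0))
  expect_warning(res3 <- ordered_cn_association(tab3), "zero-margin")
  expect_error(ordered_cn_association(matrix(c(1, 2), 1, 2)), "2 x 2")
})

test_that("pre-specified association tests find a perfect trend", {
  samples <- paste0("s", 1:12)
  rcn <- matrix(seq(-1, 1, length.out = 12), 1,
                dimnames = list("MYC", samples))
  acn <- matrix(rep(c(2, 3, 4), each = 4), 1,
                dimnames = list("MYC", samples))
  auc <- matrix(seq(1, 0.4, length.out = 12)^1.3, 12,
                dimnames = list(samples, "paclitaxel"))
  specs <- data.frame(gene = "MYC", drug = "paclitaxel",
                      direction = "sensitizing")
  res <- test_prespecified_associations(specs, rcn, acn, auc)
  expect_lt(res$trend_p, 1e-8)
  expect_equal(res$jt_p,
               jonckheere_terpstra(split(auc[, 1], rep(1:3, each = 4)),
                                   alternative = "decreasing")$p_value)
  # exclusions can make a spec untestable
  res2 <- test_prespecified_associations(specs, rcn, acn, auc,
                                         exclude_samples = samples[1:10])
  expect_match(res2$note, "untestable")
  expect_true(is.na(res2$trend_p))
})

test_that("normal-quantile transform produces standard-normal scores", {
  x <- rexp(101)
  z <- normal_quantile_transform(x)
  expect_equal(rank(z), rank(x))
  expect_equal(mean(z), 0, tolerance = 1e-10)
  expect_equal(max(z), qnorm((101 - 0.5) / 101))
})
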