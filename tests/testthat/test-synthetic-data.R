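test_that("generators are bit-reproducible under a fixed seed", {
  cfg <- cohort_sim_config(n_patients = 3, seed = 5)
  expect_identical(simulate_multiregion_cohort(cfg),
                   simulate_multiregion_cohort(cfg))
  pc <- plate_sim_config(seed = 5, outlier_rate = 0.05)
  expect_identical(simulate_plate(pc), simulate_plate(pc))
  gc <- genotype_sim_config(n_samples = 40, seed = 5)
  expect_identical(simulate_cohort_genotypes(gc),
                   simulate_cohort_genotypes(gc))
  expect_identical(simulate_expression_cn(n_genes = 20, n_samples = 10,
                                          seed = 5),
                   simulate_expression_cn(n_genes = 20, n_samples = 10,
                                          seed = 5))
})

test_that("cohort config rejects degenerate settings", {
  expect_error(cohort_sim_config(genome = data.frame(chrom = "chr1",
                                                     length = 0)),
               "positive chromosome lengths")
  expect_error(cohort_sim_config(regions_per_patient = 1,
                                 subclonal_event_rate = 2),
               ">= 2 regions")
  # one region is fine when no subclonal events are requested
  expect_s3_class(cohort_sim_config(regions_per_patient = 1,
                                    subclonal_event_rate = 0),
                  "cohort_sim_config")
})

test_that("segment tilings cover each chromosome exactly once", {
  cfg <- cohort_sim_config(n_patients = 4, seed = 2, cn_noise_sd = 0.1)
  sim <- simulate_multiregion_cohort(cfg)
  for (p in sim$profiles) {
    for (ch in unique(p$segments$chrom)) {
      s <- p$segments[p$segments$chrom == ch, ]
      len <- cfg$genome$length[cfg$genome$chrom == ch]
      expect_equal(s$start[1], 0)
      expect_equal(s$end[nrow(s)], len)
      if (nrow(s) > 1) expect_equal(s$start[-1], s$end[-nrow(s)])
    }
  }
})

test_that("planted events respect clonal/subclonal region membership", {
  cfg <- cohort_sim_config(n_patients = 6, cn_noise_sd = 0, seed = 3)
  sim <- simulate_multiregion_cohort(cfg)
  regions_of <- function(pid)
    sum(vapply(sim$profiles, function(p) p$patient_id == pid, logical(1)))
  for (i in seq_len(nrow(sim$truth))) {
    tv <- sim$truth[i, ]
    n_reg <- regions_of(tv$patient)
    members <- as.integer(strsplit(tv$regions, ",")[[1]])
    if (tv$clonality == "clonal") {
      expect_equal(members, seq_len(n_reg))
    } else {
      expect_gte(length(members), 1)
      expect_lt(length(members), n_reg)
    }
  }
})

test_that("noiseless truth round-trips through the clonality module", {
  cfg <- cohort_sim_config(n_patients = 5, cn_noise_sd = 0, seed = 11)
  sim <- simulate_multiregion_cohort(cfg)
  pids <- unique(vapply(sim$profiles, `[[`, "", "patient_id"))
  calls <- do.call(rbind, lapply(pids, function(p) {
    pr <- Filter(function(x) x$patient_id == p, sim$profiles)
    classify_clonality(build_consensus(pr))
  }))
  rec <- recover_planted_events(calls, sim$truth)
  expect_true(all(rec$recovered))
  # recovery degrades monotonically with copy-number noise
  rate_at <- function(sd) {
    cfg <- cohort_sim_config(n_patients = 10, cn_noise_sd = sd, seed = 13)
    sim <- simulate_multiregion_cohort(cfg)
    pids <- unique(vapply(sim$profiles, `[[`, "", "patient_id"))
    calls <- do.call(rbind, lapply(pids, function(p) {
      pr <- Filter(function(x) x$patient_id == p, sim$profiles)
      classify_clonality(build_consensus(pr))
    }))
    mean(recover_planted_events(calls, sim$truth)$recovered)
  }
  expect_gte(rate_at(0.05), rate_at(0.5))
})

test_that("plate truth matches the analytic curve and flags outliers", {
  pc <- plate_sim_config(noise_cv = 0, outlier_rate = 0, seed = 4)
  sim <- simulate_plate(pc)
  tm <- pc$truth_model
  # control wells sit at the truth upper asymptote
  ctrl <- sim$plate$wells$signal[sim$plate$wells$is_control]
  expect_true(all(ctrl == tm$upper * pc$signal_scale))
  # truth AUC equals quadrature of the closed-form curve
  f <- function(x) ll5_curve(x, tm$lower, tm$upper, tm$slope,
                             log(tm$inflection), tm$asymmetry)
  ld <- range(log(pc$doses))
  expect_equal(sim$truth$auc,
               integrate(f, ld[1], ld[2])$value / diff(ld),
               tolerance = 1e-8)
  # flat truth at the upper asymptote -> AUC exactly 1 after standardization
  flat <- simulate_plate(plate_sim_config(
    truth_model = list(lower = 1, upper = 1, slope = 1, inflection = 1e-7,
                       asymmetry = 1), noise_cv = 0, seed = 1))
  r <- fit_dose_response(flat$plate)
  expect_equal(r$auc, 1, tolerance = 1e-9)
  expect_true(r$ic50_censored)
  # outliers recorded at injected indices
  pco <- plate_sim_config(noise_cv = 0.05, outlier_rate = 0.1, seed = 8)
  simo <- simulate_plate(pco)
  expect_true(all(simo$truth$outlier_wells %in%
                    which(!simo$plate$wells$is_control)))
  expect_error(plate_sim_config(doses = 10^c(-8, -7, -6)),
               "4 distinct doses")
})

test_that("truth AUC is recovered within 0.05 on noisy plates", {
  ok <- 0
  for (seed in 1:60) {
    sim <- simulate_plate(plate_sim_config(noise_cv = 0.05, seed = seed))
    r <- fit_dose_response(sim$plate)
    if (abs(r$auc - sim$truth$auc) <= 0.05) ok <- ok + 1
  }
  expect_gte(ok / 60, 0.9)
})

test_that("genotype generator plants the co-occurrence and nothing else", {
  cfg <- genotype_sim_config(n_samples = 4000, co_occurrence_log_odds = 1.5,
                             baseline_scna_rate = 0.15, seed = 9)
  g <- simulate_cohort_genotypes(cfg)
  alt <- g$truth$altered
  myc <- g$truth$myc_altered
  panel <- cfg$gene_panel
  in_rate <- mean(alt[panel$pathway == "PI3K_RAS", myc])
  in_rate0 <- mean(alt[panel$pathway == "PI3K_RAS", !myc])
  out_rate <- mean(alt[panel$pathway == "other", myc])
  out_rate0 <- mean(alt[panel$pathway == "other", !myc])
  planted <- plogis(qlogis(0.15) + 1.5)
  expect_equal(in_rate, planted, tolerance = 0.03)
  expect_equal(in_rate0, 0.15, tolerance = 0.03)
  expect_equal(out_rate, 0.15, tolerance = 0.03)
  expect_equal(out_rate0, 0.15, tolerance = 0.03)
  expect_error(genotype_sim_config(gene_panel = data.frame()),
               "empty gene panel")
  # empty marker group refuses the permutation test with a clear error
  g0 <- simulate_cohort_genotypes(genotype_sim_config(
    n_samples = 50, myc_amp_fraction = 0, seed = 2))
  labels <- setNames(cfg$gene_panel$pathway, cfg$gene_panel$gene)
  expect_error(permutation_cooccurrence_test(g0$matrix, "MYC", labels),
               "empty")
})

test_that("expression generator couples expression to CN as configured", {
  # effect 1, no noise -> perfect per-gene Spearman correlation
  s <- simulate_expression_cn(n_genes = 12, n_samples = 30,
                              groups = "g", effect_sizes = c(g = 1),
                              noise_sd = 0, seed = 2)
  rho <- sapply(seq_len(12), function(i)
    cor(s$expr[i, ], s$cn[i, ], method = "spearman"))
  expect_equal(rho, rep(1, 12))
  # effect 0 -> correlations consistent with the null at this n
  s0 <- simulate_expression_cn(n_genes = 300, n_samples = 50,
                               groups = "g", effect_sizes = c(g = 0),
                               seed = 3)
  rho0 <- sapply(seq_len(300), function(i)
    cor(s0$expr[i, ], s0$cn[i, ], method = "spearman"))
  expect_lt(abs(mean(rho0)), 0.03)
  expect_equal(sd(rho0), 1 / sqrt(49), tolerance = 0.25)
  # methylation is negatively coupled to the CN-expression effect
  s2 <- simulate_expression_cn(n_genes = 400, n_samples = 20, seed = 4)
  meth_by_group <- tapply(rowMeans(s2$meth), s2$gene_groups, mean)
  expect_lt(meth_by_group[["driver_prevalent"]],
            meth_by_group[["nondriver_nonprevalent"]])
  expect_error(simulate_expression_cn(groups = c("a", "b"),
                                      effect_sizes = c(a = 1)),
               "effect_sizes")
})
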