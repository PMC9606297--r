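clean_plate <- function(seed = 1, noise_cv = 0, outlier_rate = 0, ...) {
  simulate_plate(plate_sim_config(noise_cv = noise_cv,
                                  outlier_rate = outlier_rate, seed = seed,
                                  ...))
}

test_that("standardization divides by the control median", {
  wells <- data.frame(dose = c(0, 0, 0, 10^(-8:-5)),
                      replicate = 1,
                      signal = c(900, 1000, 1100, 500, 400, 300, 200),
                      is_control = c(TRUE, TRUE, TRUE, rep(FALSE, 4)))
  p <- standardize_plate(dose_plate(wells))
  expect_equal(p$wells$response[4], 0.5)
  expect_equal(median(p$wells$response[p$wells$is_control]), 1)
  # all wells equal -> all standardized to 1
  wells$signal <- 800
  expect_true(all(standardize_plate(dose_plate(wells))$wells$response == 1))
  # zero control median rejected
  wells$signal[1:3] <- 0
  expect_error(standardize_plate(dose_plate(wells)), "control median")
})

test_that("standardized response, AUC and IC50 are scale equivariant", {
  sim <- clean_plate(seed = 3, noise_cv = 0.05)
  r1 <- fit_dose_response(sim$plate)
  scaled <- sim$plate
  scaled$wells$signal <- scaled$wells$signal * 37.5
  r2 <- fit_dose_response(scaled)
  expect_equal(r1$responses, r2$responses)
  expect_equal(r1$auc, r2$auc)
  expect_equal(r1$ic50, r2$ic50)
})

test_that("outlier screen flags an injected spike and only it", {
  hits <- 0
  for (seed in 1:50) {
    sim <- clean_plate(seed = seed, noise_cv = 0.05)
    p <- standardize_plate(sim$plate)
    test <- !p$wells$is_control
    set.seed(seed + 1000)
    spike <- sample(which(test), 1)
    p$wells$response[spike] <- p$wells$response[spike] * 5
    fl <- flag_outliers(log(p$wells$dose[test]), p$wells$response[test])
    if (identical(which(fl$outlier), match(spike, which(test))))
      hits <- hits + 1
  }
  expect_gte(hits, 45)  # >= 90% exact single-well detection
})

test_that("clean and identical plates produce no outlier flags", {
  sim <- clean_plate(seed = 2)
  p <- standardize_plate(sim$plate)
  test <- !p$wells$is_control
  fl <- flag_outliers(log(p$wells$dose[test]), p$wells$response[test])
  expect_false(any(fl$outlier))
  # all-identical responses: zero residuals, all weights 1
  fl2 <- flag_outliers(log(p$wells$dose[test]), rep(1, sum(test)))
  expect_true(all(fl2$weights == 1))
  expect_false(any(fl2$outlier))
})

test_that("AUC from a flagged-spike plate stays close to the clean AUC", {
  sim <- clean_plate(seed = 9, noise_cv = 0.03)
  r_clean <- fit_dose_response(sim$plate)
  spiked <- sim$plate
  idx <- which(!spiked$wells$is_control)[10]
  spiked$wells$signal[idx] <- spiked$wells$signal[idx] * 5
  r_spiked <- fit_dose_response(spiked)
  expect_true(r_spiked$outlier[match(idx, which(!spiked$wells$is_control))] ||
                r_spiked$n_outliers > 0)
  expect_lt(abs(r_clean$auc - r_spiked$auc), 0.02)
})

test_that("spline fit reproduces a noiseless log-logistic curve", {
  sim <- clean_plate(seed = 1)
  p <- standardize_plate(sim$plate)
  test <- !p$wells$is_control
  ld <- log(p$wells$dose[test])
  fit <- fit_monotone_spline(ld, p$wells$response[test])
  tm <- sim$truth$model
  grid <- seq(min(ld), max(ld), length.out = 200)
  truth <- ll5_curve(grid, tm$lower, tm$upper, tm$slope,
                     log(tm$inflection), tm$asymmetry)
  expect_lt(max(abs(predict(fit, grid) - truth)), 0.02)
  expect_error(fit_monotone_spline(ld[1:3], rep(1, 3)), "4 distinct")
})

test_that("I-spline AUC equals numeric integration of the fitted curve", {
  for (seed in 1:10) {
    sim <- clean_plate(seed = seed, noise_cv = 0.08)
    r <- fit_dose_response(sim$plate)
    expect_equal(r$auc, oracle_trapezoid_auc(r$fit), tolerance = 1e-5)
  }
  # constant curves
  x <- log(10^seq(-8.5, -5, 0.5))
  for (const in c(1, 0)) {
    f <- fit_monotone_spline(x, rep(const, length(x)))
    expect_equal(auc_mspline(f), const, tolerance = 1e-9)
  }
})

test_that("AUC is monotone in pointwise curve level", {
  x <- rep(log(10^seq(-8.5, -5, 0.5)), each = 3)
  y_hi <- ll5_curve(x, 0.3, 1, 1.2, log(1e-7))
  y_lo <- y_hi - 0.15
  expect_gt(auc_mspline(fit_monotone_spline(x, y_hi)),
            auc_mspline(fit_monotone_spline(x, y_lo)))
})

test_that("IC50 crosses at the right dose and censors correctly", {
  x <- log(10^seq(-8.5, -5, 0.5))
  # straight line from 1 at min to 0 at max: IC50 at the log-midpoint
  y <- 1 - (x - min(x)) / diff(range(x))
  fit <- fit_monotone_spline(x, y)
  ic <- ic50_mspline(fit)
  expect_equal(ic$log_ic50, mean(range(x)), tolerance = 1e-6)
  # curve always above 0.5 -> censored
  fit_hi <- fit_monotone_spline(x, rep(0.9, length(x)))
  expect_true(ic50_mspline(fit_hi)$censored)
  # noiseless truth with IC50 at the 3rd dose is recovered there
  doses <- 10^seq(-8.5, -5, 0.5)
  sim <- clean_plate(seed = 5,
                     truth_model = list(lower = 0, upper = 1, slope = 1.2,
                                        inflection = doses[3],
                                        asymmetry = 1))
  r <- fit_dose_response(sim$plate)
  expect_equal(r$log_ic50, log(doses[3]), tolerance = 0.25)
  # first (lowest-dose) crossing is returned when there are several
  x2 <- seq(0, 10, length.out = 30)
  y2 <- 0.5 + 0.4 * cos(x2)
  f2 <- fit_monotone_spline(x2, y2, n_interior = 8)
  expect_lt(ic50_mspline(f2)$log_ic50, pi)
})

test_that("5PL cross-check recovers a noiseless 5PL truth", {
  x <- rep(log(10^seq(-8.5, -5, 0.5)), each = 3)
  truth <- list(lower = 0.12, upper = 0.98, slope = 1.4, e = log(2e-7),
                f = 1.3)
  y <- ll5_curve(x, truth$lower, truth$upper, truth$slope, truth$e,
                 truth$f)
  fit <- fit_loglogistic5(x, y)
  expect_true(fit$converged)
  for (nm in c("lower", "upper", "slope", "f"))
    expect_equal(fit$parameters[[nm]], truth[[nm]], tolerance = 1e-3)
  expect_equal(fit$parameters$e, truth$e, tolerance = 1e-3)
  # spline and 5PL agree on clean plates
  sim <- clean_plate(seed = 4, noise_cv = 0.04)
  r <- fit_dose_response(sim$plate, crosscheck = TRUE)
  expect_lt(r$auc_discrepancy, 0.05)
  expect_equal(r$log_ic50, r$ll5$log_ic50, tolerance = log(10) / 4)
})

test_that("heatmap inputs give unit Z-scores and oracle-equal linkage", {
  set.seed(21)
  auc <- matrix(runif(48, 0.2, 1), 8, 6,
                dimnames = list(paste0("s", 1:8), paste0("d", 1:6)))
  auc[, 6] <- auc[, 5]  # two identical drugs
  h <- drug_response_heatmap_inputs(auc)
  expect_equal(unname(colMeans(h$z)), rep(0, 6))
  expect_equal(unname(apply(h$z, 2, sd)), rep(1, 6))
  expect_equal(h$drug_hclust$height[1], 0)  # identical drugs merge first
  rho <- cor(auc, method = "spearman")
  expect_equal(sort(h$drug_hclust$height),
               oracle_complete_linkage_heights(dist(rho)),
               tolerance = 1e-12)
  aucc <- auc; aucc[, 2] <- 0.5
  expect_warning(drug_response_heatmap_inputs(aucc), "constant")
})
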