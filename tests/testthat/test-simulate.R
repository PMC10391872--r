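test_that("the default design matches the emulated study conditions", {
  d <- sim_design()
  expect_identical(d$M, 100)
  expect_identical(sum(d$n_per_evaluator), 4000)
  expect_identical(sum(d$true_outlier), 8L)       # five at 75, three at 70
  expect_identical(which(d$true_outlier), 1:8)
  expect_identical(truncated_mean(d$beta, 0.1), 67)
  expect_identical(d$gamma, c(-2.7, 0.03, 3.3, 10.3))
  expect_error(sim_design(M = 3, beta = c(1, 2)), class = "evalqc_domain_error")
  expect_error(sim_design(sigma = 0), class = "evalqc_domain_error")
})

test_that("the generator reproduces its own design parameters", {
  d <- sim_design(M = 10, n_per_evaluator = 200,
                  beta = c(rep(75, 1), rep(67, 9)), sigma = 6)
  tab <- simulate_measurements(d, seed = 55)
  expect_identical(nrow(tab), 2000L)
  # residuals reconstructed from the generating formula have SD ~ sigma
  g <- d$gamma
  mu <- g[1] * tab$age + g[2] * tab$age^2 + g[3] * (tab$hearing_status == "very_good") +
    g[4] * (tab$hearing_status == "little_trouble") + d$beta[tab$evaluator_id]
  expect_equal(sd(tab$outcome - mu), 6, tolerance = 0.3)
  # block mean difference between a normal and the outlier evaluator ~ -8
  m1 <- mean(tab$outcome[tab$evaluator_id == 1])
  m9 <- mean(tab$outcome[tab$evaluator_id == 9])
  expect_equal(m9 - m1, -8, tolerance = 2)
  # noiseless limit: OLS recovers beta exactly
  d0 <- sim_design(M = 4, n_per_evaluator = 30, beta = c(70, 67, 67, 67),
                   sigma = 1e-9)
  t0 <- simulate_measurements(d0, seed = 9)
  eff <- extract_effects(
    fit_evaluators(t0, covariates = ~ age + I(age^2) + hearing_status))
  expect_equal(unname(eff$beta), d0$beta, tolerance = 1e-5)
  # seeded reproducibility
  expect_identical(simulate_measurements(d, seed = 13),
                   simulate_measurements(d, seed = 13))
})

test_that("the bilateral generator has the stated correlation structure", {
  d <- sim_design(M = 5, n_per_evaluator = 400, beta = rep(67, 5), sigma = 8,
                  bilateral = TRUE, rho = 0.7)
  tab <- simulate_measurements(d, seed = 77)
  expect_identical(nrow(tab), 4000L)
  # residual correlation (the outcome correlation additionally carries the
  # shared participant-level mean structure)
  resid_wide <- function(tb, ds) {
    g <- ds$gamma
    mu <- g[1] * tb$age + g[2] * tb$age^2 + g[3] * (tb$hearing_status == "very_good") +
      g[4] * (tb$hearing_status == "little_trouble") + ds$beta[tb$evaluator_id]
    tb$resid <- tb$outcome - mu
    tidyr::pivot_wider(tb, id_cols = "participant_id",
                       names_from = "measurement_index", values_from = "resid")
  }
  wide <- resid_wide(tab, d)
  expect_equal(cor(wide$`1`, wide$`2`), 0.7, tolerance = 0.05)
  expect_equal(sd(wide$`1`), 8, tolerance = 0.4)
  expect_equal(sd(wide$`2`), 8, tolerance = 0.4)
  # rho = 0: per-ear margins behave like the single-measurement generator
  d0 <- sim_design(M = 5, n_per_evaluator = 400, beta = rep(67, 5), sigma = 8,
                   bilateral = TRUE, rho = 0)
  t0 <- simulate_measurements(d0, seed = 78)
  w0 <- resid_wide(t0, d0)
  expect_lt(abs(cor(w0$`1`, w0$`2`)), 0.07)
  ds <- sim_design(M = 5, n_per_evaluator = 400, beta = rep(67, 5), sigma = 8)
  ts <- simulate_measurements(ds, seed = 79)
  for (k in 1:2) {
    expect_equal(sd(t0$outcome[t0$measurement_index == k]), sd(ts$outcome),
                 tolerance = 0.06 * sd(ts$outcome))
  }
})

test_that("replicate_study aggregates detection and FDR summaries", {
  d <- tiny_design(sigma = 6, M = 12, n = 25)
  s <- replicate_study(d, n_replicates = 8, power_grid = c(0.5, 0.8, 0.95),
                       c = 5, delta = 0.1, seed = 99)
  expect_identical(nrow(s$curve), 3L)
  expect_identical(nrow(s$evaluators), 36L)
  expect_true(all(s$curve$fdr_estimated >= 0 & s$curve$fdr_estimated <= 1))
  expect_true(all(s$evaluators$prop_detected >= s$evaluators$prop_detected_adjusted))
  expect_true(all(s$evaluators$prop_detected >= 0 & s$evaluators$prop_detected <= 1))
  # the two strong outliers dominate detections at high power
  top <- dplyr::filter(s$evaluators, power == 0.95, evaluator <= 2)
  expect_gte(mean(top$prop_detected), 0.9)
  # reproducibility under the master seed
  s2 <- replicate_study(d, n_replicates = 8, power_grid = c(0.5, 0.8, 0.95),
                        c = 5, delta = 0.1, seed = 99)
  expect_identical(s$curve, s2$curve)
  expect_identical(s$evaluators, s2$evaluators)
})

test_that("fixed-level rejections under a null design hit the nominal rate", {
  d <- sim_design(M = 20, n_per_evaluator = 25, beta = rep(67, 20), sigma = 8)
  s <- replicate_study(d, n_replicates = 25, power_grid = c(0.5),
                       c = 5, delta = 0.1, seed = 42, fixed_alpha = 0.05)
  rate <- mean(s$fixed$prop_detected)
  # 20 x 25 = 500 tests; 3 MC SDs of a 0.05 proportion ~ 0.03
  expect_lt(abs(rate - 0.05), 0.03)
})
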