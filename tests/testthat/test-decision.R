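# one moderately-sized fit shared by the decision-layer tests
local_report_inputs <- local({
  d <- tiny_design(sigma = 4, M = 12, n = 25)
  tab <- simulate_measurements(d, seed = 101)
  eff <- extract_effects(
    fit_evaluators(tab, covariates = ~ age + I(age^2) + hearing_status))
  list(design = d, tab = tab, effects = eff,
       tests = evaluator_tests(eff, delta = 0.1))
})

test_that("each curve point composes alpha_for_power with estimate_fdr", {
  tests <- local_report_inputs$tests
  curve <- decision_curve(tests, c = 5, power_grid = seq(0.2, 0.9, by = 0.1))
  lambda <- 25 / tests$std.error^2
  for (g in seq_len(nrow(curve))) {
    alpha <- alpha_for_power(lambda, curve$power[g])
    expect_equal(unname(attr(curve, "alpha")[, g]), alpha, tolerance = 1e-12)
    expect_equal(curve$fdr_estimate[g],
                 as.numeric(estimate_fdr(alpha, tests$p.value)))
  }
  # with clear outliers present the estimated FDR trends upward in power
  expect_gte(curve$fdr_estimate[nrow(curve)], curve$fdr_estimate[1])
  expect_error(decision_curve(tests, power_grid = c(0.5, 0.4)),
               class = "evalqc_domain_error")
})

test_that("identical effects with tiny variances give a zero-FDR floor", {
  eff <- structure(list(beta = setNames(rep(5, 6), letters[1:6]),
                        Sigma = diag(1e-6, 6),
                        evaluator_labels = letters[1:6],
                        n_per_evaluator = setNames(rep(20, 6), letters[1:6])),
                   class = "evaluator_effects")
  curve <- decision_curve(evaluator_tests(eff, delta = 0), c = 5,
                          power_grid = c(0.1, 0.2, 0.3))
  expect_identical(curve$n_rejected, rep(0L, 3))
  expect_identical(curve$fdr_estimate, rep(0, 3))
})

test_that("operating points are selected by power or by tolerable FDR", {
  curve <- decision_curve(local_report_inputs$tests, c = 5,
                          power_grid = seq(0.1, 0.9, by = 0.05))
  op <- select_operating_point(curve, power = 0.8)
  expect_equal(op$power, 0.8)
  expect_identical(op$alpha, attr(curve, "alpha")[, which(curve$power == 0.8)])
  target <- stats::median(curve$fdr_estimate)
  op2 <- select_operating_point(curve, target_fdr = target)
  expect_lte(op2$fdr_estimate, target)
  later <- curve$power > op2$power
  expect_true(all(curve$fdr_estimate[later] > target))
  expect_error(select_operating_point(curve, target_fdr = -0.1),
               class = "evalqc_range_error")
  expect_error(select_operating_point(curve), class = "evalqc_domain_error")
})

test_that("detect_outliers runs end to end and respects set nesting", {
  report <- detect_outliers(local_report_inputs$tab,
                            covariates = ~ age + I(age^2) + hearing_status,
                            delta = 0.1, c = 5, power = 0.9)
  expect_s3_class(report, "outlier_report")
  expect_true(all(report$outliers_adjusted %in% report$outliers))
  expect_true(all(report$tests$rejected_adjusted <= report$tests$rejected))
  # strong outliers (true effect 75 vs normal 67, sigma 4) are flagged
  expect_true(all(c("1", "2") %in% report$outliers))
  # delta = 0 also runs; flagged sets may differ
  report0 <- detect_outliers(local_report_inputs$tab,
                             covariates = ~ age + I(age^2) + hearing_status,
                             delta = 0, c = 5, power = 0.9)
  expect_s3_class(report0, "outlier_report")
  # fixed-level baseline mode
  reportf <- detect_outliers(local_report_inputs$tab,
                             covariates = ~ age + I(age^2) + hearing_status,
                             delta = 0.1, fixed_alpha = 0.05)
  expect_true(all(reportf$tests$alpha == 0.05))
  expect_identical(glance(reportf)$n.flagged, sum(reportf$tests$p.value < 0.05))
})

test_that("a stricter alternative shrinks the flagged set", {
  tab <- local_report_inputs$tab
  run <- function(cc) detect_outliers(tab,
                                      covariates = ~ age + I(age^2) + hearing_status,
                                      delta = 0.1, c = cc, power = 0.9)
  r5 <- run(5); r20 <- run(20)
  expect_true(all(r20$outliers %in% r5$outliers))
  expect_lte(length(r20$outliers), length(r5$outliers))
})

test_that("null data rarely yields adjusted discoveries at power 0.8", {
  d_null <- sim_design(M = 15, n_per_evaluator = 20, beta = rep(67, 15), sigma = 8)
  n_empty <- sum(vapply(1:12, function(r) {
    tab <- simulate_measurements(d_null, seed = 700 + r)
    rep <- detect_outliers(tab, covariates = ~ age + I(age^2) + hearing_status,
                           delta = 0.1, c = 5, power = 0.8)
    length(rep$outliers_adjusted) == 0
  }, logical(1)))
  expect_gte(n_empty, 9)
})

test_that("errors from inner stages are labelled with the failing stage", {
  d <- toy_table()
  d$outcome[1] <- NA
  err <- tryCatch(detect_outliers(d, power = 0.8), error = identity)
  expect_match(conditionMessage(err), "stage-1 regression")
})
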