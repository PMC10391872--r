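#' FDR vs power decision curve
#'
#' For each target power \eqn{\phi} on a grid, solves the evaluator-specific
#' significance levels \eqn{\alpha_j(\phi)} at the alternative
#' \eqn{|L_j^T\beta| = c} and estimates the FDR of the resulting rejections
#' with [estimate_fdr()]. Plotting \eqn{\hat{Q}(\phi)} against \eqn{\phi}
#' shows the trade-off between detecting more candidate outliers and making
#' more false discoveries; an operating point is then chosen with
#' [select_operating_point()]. Points are emitted raw (no smoothing).
#'
#' @param tests An `evaluator_tests` tibble from [evaluator_tests()].
#' @param c Alternative magnitude in outcome units.
#' @param power_grid Ascending powers in (0, 1); the default grid is
#'   0.10 to 0.95 in steps of 0.01.
#' @return A tibble of class `decision_curve`: `power`, `fdr_estimate`,
#'   `n_rejected`. The M x G matrix of per-point \eqn{\alpha_j} vectors is in
#'   attribute `"alpha"`; the source tests in attribute `"tests"`.
#' @export
decision_curve <- function(tests, c = 5,
                           power_grid = seq(0.10, 0.95, by = 0.01)) {
  stopifnot(inherits(tests, "evaluator_tests"))
  if (any(power_grid <= 0 | power_grid >= 1) || is.unsorted(power_grid, strictly = TRUE)) {
    abort("`power_grid` must be strictly ascending within (0, 1).",
          class = "evalqc_domain_error")
  }
  lambda <- c^2 / tests$std.error^2
  p <- tests$p.value
  alpha_mat <- vapply(power_grid, function(phi) alpha_for_power(lambda, phi),
                      numeric(length(lambda)))
  alpha_mat <- matrix(alpha_mat, nrow = length(lambda),
                      dimnames = list(tests$evaluator, NULL))
  qhat <- vapply(seq_along(power_grid), function(g) {
    as.numeric(estimate_fdr(alpha_mat[, g], p))
  }, numeric(1))
  nrej <- colSums(p < alpha_mat)
  out <- tibble::tibble(power = power_grid, fdr_estimate = qhat,
                        n_rejected = as.integer(nrej))
  attr(out, "alpha") <- alpha_mat
  attr(out, "c") <- c
  attr(out, "tests") <- tests
  class(out) <- c("decision_curve", class(out))
  out
}

#' Choose an operating point on a decision curve
#'
#' Either fix the power (`power = 0.9`: use that grid point) or fix a
#' tolerable FDR (`target_fdr = 0.5`: use the **largest** grid power whose
#' estimated FDR does not exceed the target).
#'
#' @param curve A `decision_curve`.
#' @param power Target power; must lie on the curve's grid (nearest grid
#'   point within 1e-8 is used).
#' @param target_fdr Tolerable estimated FDR.
#' @return A list: `power`, `fdr_estimate`, `alpha` (per-evaluator levels at
#'   the chosen point), `n_rejected`.
#' @export
select_operating_point <- function(curve, power = NULL, target_fdr = NULL) {
  stopifnot(inherits(curve, "decision_curve"))
  if (is.null(power) == is.null(target_fdr)) {
    abort("Supply exactly one of `power` or `target_fdr`.",
          class = "evalqc_domain_error")
  }
  if (!is.null(power)) {
    g <- which(abs(curve$power - power) < 1e-8)
    if (!length(g)) {
      abort(sprintf("power = %.3f is not on the curve grid [%.2f, %.2f].",
                    power, min(curve$power), max(curve$power)),
            class = "evalqc_range_error")
    }
    g <- g[1]
  } else {
    ok <- which(curve$fdr_estimate <= target_fdr)
    if (!length(ok)) {
      abort(sprintf("target_fdr = %.3f is unattainable; achievable estimated FDR range is [%.3f, %.3f].",
                    target_fdr, min(curve$fdr_estimate), max(curve$fdr_estimate)),
            class = "evalqc_range_error")
    }
    g <- max(ok)
  }
  list(power = curve$power[g],
       fdr_estimate = curve$fdr_estimate[g],
       alpha = attr(curve, "alpha")[, g],
       n_rejected = curve$n_rejected[g])
}

#' Run the full two-stage outlier-evaluator detection procedure
#'
#' Convenience wrapper: stage-one fit ([fit_evaluators()]), per-evaluator
#' Wald tests against the (truncated) mean effect ([evaluator_tests()]),
#' power calibration and decision curve ([decision_curve()]), operating-point
#' selection, and FDR-based pruning of the rejections ([fdr_adjust()]).
#'
#' @inheritParams fit_evaluators
#' @param delta Truncation fraction for the reference mean (default 0.1).
#' @param c Alternative magnitude in outcome units (default 5).
#' @param power,target_fdr Operating point: supply one of the two (see
#'   [select_operating_point()]).
#' @param fixed_alpha If non-`NULL`, bypass calibration and reject every test
#'   at this single level (conventional baseline, e.g. 0.05).
#' @param power_grid Grid for the decision curve.
#' @return An object of class `outlier_report`: elements `fit`, `tests`
#'   (calibrated, with `rejected` and `rejected_adjusted`), `curve`,
#'   `operating` (chosen point), `outliers` and `outliers_adjusted`
#'   (evaluator labels), `fdr_estimate`, and the settings used. [tidy()]
#'   returns the per-evaluator table; [glance()] a one-row summary.
#' @export
detect_outliers <- function(data,
                            covariates = NULL,
                            measurement_covariates = NULL,
                            method = c("ols", "gee"),
                            working_correlation = c("independent",
                                                    "exchangeable",
                                                    "unstructured"),
                            delta = 0.1,
                            c = 5,
                            power = NULL,
                            target_fdr = NULL,
                            fixed_alpha = NULL,
                            power_grid = seq(0.10, 0.95, by = 0.01),
                            outcome = "outcome",
                            evaluator = "evaluator_id",
                            participant = "participant_id",
                            measurement_index = NULL,
                            control = list()) {
  stage <- "stage-1 regression"
  report <- tryCatch({
    fit <- fit_evaluators(data, covariates = covariates,
                          measurement_covariates = measurement_covariates,
                          method = method,
                          working_correlation = working_correlation,
                          outcome = outcome, evaluator = evaluator,
                          participant = participant,
                          measurement_index = measurement_index,
                          control = control)
    stage <- "contrast tests"
    effects <- extract_effects(fit)
    tests <- evaluator_tests(effects, delta = delta)
    stage <- "power calibration"
    curve <- decision_curve(tests, c = c, power_grid = power_grid)
    if (!is.null(fixed_alpha)) {
      cal <- calibrate_tests(tests, c = c, fixed_alpha = fixed_alpha)
      op <- list(power = NA_real_, fdr_estimate = as.numeric(attr(cal, "fdr_estimate")),
                 alpha = cal$alpha, n_rejected = sum(cal$rejected))
    } else {
      if (is.null(power) && is.null(target_fdr)) power <- 0.9
      op <- select_operating_point(curve, power = power, target_fdr = target_fdr)
      cal <- calibrate_tests(tests, c = c, power = op$power)
    }
    stage <- "FDR adjustment"
    cal <- fdr_adjust(cal)
    structure(
      list(fit = fit,
           tests = cal,
           curve = curve,
           operating = op,
           outliers = cal$evaluator[cal$rejected],
           outliers_adjusted = cal$evaluator[cal$rejected_adjusted],
           fdr_estimate = as.numeric(attr(cal, "fdr_estimate")),
           delta = delta, c = c, fixed_alpha = fixed_alpha),
      class = "outlier_report")
  }, error = function(e) {
    if (inherits(e, "evalqc_stage_error")) stop(e)
    abort(sprintf("[%s] %s", stage, conditionMessage(e)),
          class = c("evalqc_stage_error", class(e)[startsWith(class(e), "evalqc")]),
          parent = e)
  })
  report
}

#' @export
print.outlier_report <- function(x, ...) {
  cat("<outlier_report>\n")
  cat(sprintf("  evaluators tested: %d (delta = %.2f, alternative c = %g)\n",
              nrow(x$tests), x$delta, x$c))
  if (is.null(x$fixed_alpha)) {
    cat(sprintf("  operating point: power %.2f, estimated FDR %.3f\n",
                x$operating$power, x$operating$fdr_estimate))
  } else {
    cat(sprintf("  fixed significance level %.3f, estimated FDR %.3f\n",
                x$fixed_alpha, x$operating$fdr_estimate))
  }
  cat(sprintf("  flagged: %s\n",
              if (length(x$outliers)) paste(x$outliers, collapse = ", ") else "(none)"))
  cat(sprintf("  flagged after FDR pruning: %s\n",
              if (length(x$outliers_adjusted))
                paste(x$outliers_adjusted, collapse = ", ") else "(none)"))
  invisible(x)
}

#' @rdname detect_outliers
#' @param x,object An `outlier_report`.
#' @param ... Unused.
#' @export
tidy.outlier_report <- function(x, ...) {
  out <- tibble::as_tibble(x$tests)
  class(out) <- class(tibble::tibble())
  out
}

#' @rdname detect_outliers
#' @export
glance.outlier_report <- function(x, ...) {
  tibble::tibble(
    n.evaluators = nrow(x$tests),
    delta = x$delta,
    c = x$c,
    power = x$operating$power,
    fdr.estimate = x$fdr_estimate,
    n.flagged = length(x$outliers),
    n.flagged.adjusted = length(x$outliers_adjusted)
  )
}
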