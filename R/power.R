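#' Power of the 1-df Wald test at a given significance level
#'
#' Under the alternative \eqn{|L^T\beta| = c} the Wald statistic follows a
#' noncentral chi-square distribution with 1 degree of freedom and
#' noncentrality \eqn{\lambda = c^2 / (L^T\hat\Sigma L)}. The power at
#' two-sided level \eqn{\alpha} is
#' \deqn{\phi = 1 - F_{\chi^2_1(\lambda)}(\chi^2_{1,1-\alpha}).}
#' At \eqn{\lambda = 0} the power equals \eqn{\alpha}.
#'
#' @param lambda Noncentrality parameter(s), `>= 0`. Vectorised.
#' @param alpha Significance level(s) in (0, 1). Vectorised.
#' @return Power value(s) in (0, 1).
#' @export
power_at_alpha <- function(lambda, alpha) {
  if (any(lambda < 0) || any(!is.finite(lambda))) {
    abort("`lambda` must be finite and >= 0.", class = "evalqc_domain_error")
  }
  if (any(alpha <= 0 | alpha >= 1)) {
    abort("`alpha` must be in (0, 1).", class = "evalqc_domain_error")
  }
  # upper-tail quantile directly: 1 - alpha underflows for tiny alpha
  crit <- qchisq(alpha, df = 1, lower.tail = FALSE)
  pchisq(crit, df = 1, ncp = lambda, lower.tail = FALSE)
}

#' Significance level attaining a target power
#'
#' Closed-form inverse of [power_at_alpha()] in \eqn{\alpha}:
#' \deqn{\alpha = 1 - F_{\chi^2_1}\left(F^{-1}_{\chi^2_1(\lambda)}(1-\phi)\right).}
#' Each evaluator gets its own level because the contrast variances — hence
#' the \eqn{\lambda_j} — differ across evaluators.
#'
#' @param lambda Noncentrality parameter(s), `> 0`. Vectorised.
#' @param phi Target power in (0, 1).
#' @return Significance level(s) in (0, 1); `power_at_alpha(lambda, alpha)`
#'   round-trips to `phi` within 1e-8.
#' @export
alpha_for_power <- function(lambda, phi) {
  if (any(lambda <= 0) || any(!is.finite(lambda))) {
    abort("`lambda` must be finite and > 0 (at lambda = 0 no level below the power itself attains it).",
          class = "evalqc_domain_error")
  }
  if (any(phi <= 0 | phi >= 1)) {
    abort("`phi` must be in (0, 1).", class = "evalqc_domain_error")
  }
  crit <- qchisq1_ncp(1 - phi, lambda)
  pchisq(crit, df = 1, lower.tail = FALSE)
}

# Quantile of the noncentral chi-square with 1 df. For df = 1 the
# distribution is exactly (Z + sqrt(lambda))^2, so the CDF is
# F(x) = Phi(sqrt(x) - a) - Phi(-sqrt(x) - a) with a = sqrt(lambda).
# Solved for s = sqrt(x) by safeguarded Newton, vectorised over lambda;
# much faster than stats::qchisq(..., ncp =) and equal to it within ~1e-10.
qchisq1_ncp <- function(p, lambda) {
  n <- max(length(p), length(lambda))
  p <- rep_len(p, n); a <- sqrt(rep_len(lambda, n))
  s <- pmax(a + qnorm(p), 1e-12)   # upper-tail-only start
  lo <- rep(0, n); hi <- rep(Inf, n)
  for (it in 1:100) {
    g <- pnorm(s - a) - pnorm(-s - a) - p
    lo <- ifelse(g < 0, pmax(lo, s), lo)
    hi <- ifelse(g > 0, pmin(hi, s), hi)
    dg <- stats::dnorm(s - a) + stats::dnorm(s + a)
    step <- g / pmax(dg, .Machine$double.xmin)
    s_new <- s - step
    bad <- !is.finite(s_new) | s_new <= lo | s_new >= hi
    s_new[bad] <- ifelse(is.finite(hi[bad]), (lo[bad] + hi[bad]) / 2,
                         2 * pmax(s[bad], 1))
    if (max(abs(s_new - s)) < 1e-12 * max(1, max(s_new))) { s <- s_new; break }
    s <- s_new
  }
  s^2
}

#' Noncentrality parameter of a contrast at a stated alternative
#'
#' \eqn{\lambda = c^2 / (L^T\hat\Sigma L)}, where `c` is the subject-matter
#' alternative (e.g. 5 dB HL, one audiometric testing step).
#'
#' @param contrast Numeric M-vector of contrast weights.
#' @param Sigma M x M covariance matrix of the evaluator effects.
#' @param c Alternative magnitude, `> 0`, in outcome units.
#' @return The noncentrality parameter (scalar).
#' @export
noncentrality <- function(contrast, Sigma, c) {
  if (c <= 0) abort("`c` must be > 0.", class = "evalqc_domain_error")
  v <- drop(crossprod(contrast, Sigma %*% contrast))
  if (!is.finite(v) || v <= 0) {
    abort(sprintf("Degenerate contrast variance (L'Sigma L = %.3g).", v),
          class = "evalqc_degenerate_variance_error")
  }
  c^2 / v
}

#' Calibrate evaluator-specific significance levels to a target power
#'
#' Adds to a test table the noncentrality \eqn{\lambda_j = c^2 /
#' (L_j^T\hat\Sigma L_j)}, the evaluator-specific level \eqn{\alpha_j(\phi)}
#' attaining power `power` against \eqn{|L_j^T\beta| = c}, and the resulting
#' rejection indicator \eqn{p_j < \alpha_j}. With `fixed_alpha` set, every
#' evaluator instead uses that single level (the conventional baseline).
#'
#' @param tests An `evaluator_tests` tibble from [evaluator_tests()].
#' @param c Alternative magnitude in outcome units (default 5, one 5-dB
#'   audiometric step).
#' @param power Target power \eqn{\phi} in (0, 1).
#' @param fixed_alpha If non-`NULL`, skip calibration and use this level for
#'   every evaluator.
#' @return The tibble with columns `lambda`, `alpha` and `rejected` added,
#'   plus an `fdr_estimate` attribute from [estimate_fdr()].
#' @export
calibrate_tests <- function(tests, c = 5, power = NULL, fixed_alpha = NULL) {
  stopifnot(inherits(tests, "evaluator_tests"))
  lambda <- c^2 / tests$std.error^2
  if (is.null(fixed_alpha)) {
    if (is.null(power)) {
      abort("Supply either `power` or `fixed_alpha`.", class = "evalqc_domain_error")
    }
    alpha <- alpha_for_power(lambda, power)
  } else {
    if (fixed_alpha <= 0 || fixed_alpha >= 1) {
      abort("`fixed_alpha` must be in (0, 1).", class = "evalqc_domain_error")
    }
    alpha <- rep(fixed_alpha, nrow(tests))
  }
  out <- tests
  out$lambda <- lambda
  out$alpha <- alpha
  out$rejected <- out$p.value < out$alpha
  attr(out, "delta") <- attr(tests, "delta")
  attr(out, "contrasts") <- attr(tests, "contrasts")
  attr(out, "c") <- c
  attr(out, "power") <- if (is.null(fixed_alpha)) power else NA_real_
  attr(out, "fdr_estimate") <- estimate_fdr(alpha, out$p.value)
  class(out) <- unique(c("evaluator_tests", class(out)))
  out
}
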