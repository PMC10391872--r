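#' Estimate evaluator effects by cell-means regression
#'
#' Stage one of the outlier-evaluator procedure. Fits
#' \deqn{E(Y) = \sum_{j=1}^{M} \beta_j T^{(j)} + \gamma^T X (+ \eta^T Z)}
#' with one indicator \eqn{T^{(j)}} per evaluator and **no intercept**
#' (cell-means coding), so each \eqn{\beta_j} is evaluator *j*'s adjusted mean
#' measurement. Covariates are entered as given — never centred — so that
#' zero-sum contrasts over \eqn{\beta} cancel any shared location.
#'
#' With `method = "ols"` each participant must have exactly one measurement
#' and the fit is ordinary least squares, with
#' \eqn{\widehat{Var}(\hat\theta) = \hat\sigma^2 (D^T D)^{-1}} and
#' \eqn{\hat\sigma^2} the residual mean square. With `method = "gee"`
#' measurements are clustered within participants (e.g. left and right ear)
#' and the coefficients solve the generalized estimating equation for an
#' identity link and Gaussian working variance, under an `independent`,
#' `exchangeable` or `unstructured` working correlation; the covariance is the
#' robust sandwich estimator with the participant as the cluster unit.
#'
#' @param data A long-format data frame, one row per measurement (see
#'   [validate_measurements()]).
#' @param covariates One-sided formula of participant-level covariate terms,
#'   e.g. `~ age + I(age^2) + hearing_status`. Polynomial terms and factors
#'   (expanded against their reference level) are supported. `NULL` for none.
#' @param measurement_covariates One-sided formula of measurement-level terms
#'   (e.g. `~ ear`), used with `method = "gee"`. `NULL` for none.
#' @param method `"ols"` or `"gee"`.
#' @param working_correlation Working correlation structure for GEE.
#' @param outcome,evaluator,participant Column names.
#' @param measurement_index Optional column giving the measurement position
#'   within a participant (needed for `unstructured`); defaults to row order
#'   within participant.
#' @param control List of GEE solver settings: `tol` (relative
#'   parameter-change convergence tolerance, default `1e-8`) and `maxit`
#'   (default `100`).
#'
#' @return An object of class `evaluator_fit`: the full coefficient vector
#'   (evaluator block first), its covariance matrix, evaluator labels and
#'   per-evaluator participant counts, plus fit metadata. Use [tidy()] /
#'   [glance()] for tibble summaries and [extract_effects()] for the
#'   evaluator block \eqn{\hat\beta, \hat\Sigma}.
#' @export
#' @examples
#' d <- tibble::tibble(
#'   participant_id = 1:6,
#'   evaluator_id = rep(c("a", "b"), each = 3),
#'   outcome = c(1, 2, 3, 5, 6, 7)
#' )
#' fit <- fit_evaluators(d)
#' tidy(fit)
fit_evaluators <- function(data,
                           covariates = NULL,
                           measurement_covariates = NULL,
                           method = c("ols", "gee"),
                           working_correlation = c("independent",
                                                   "exchangeable",
                                                   "unstructured"),
                           outcome = "outcome",
                           evaluator = "evaluator_id",
                           participant = "participant_id",
                           measurement_index = NULL,
                           control = list()) {
  method <- match.arg(method)
  working_correlation <- match.arg(working_correlation)
  cov_cols <- unique(c(all.vars(covariates), all.vars(measurement_covariates)))
  data <- validate_measurements(data, outcome = outcome, evaluator = evaluator,
                                participant = participant,
                                covariate_cols = intersect(cov_cols, names(data)))
  missing_cov <- setdiff(cov_cols, names(data))
  if (length(missing_cov)) {
    abort(paste0("Covariate column(s) not found: ",
                 paste(missing_cov, collapse = ", ")),
          class = "evalqc_validation_error")
  }

  ev <- data[[evaluator]]
  labels <- if (is.factor(ev)) levels(droplevels(ev)) else sort(unique(ev))
  fct <- factor(as.character(ev), levels = as.character(labels))
  part <- data[[participant]]
  n_per_evaluator <- tapply(part, fct, function(p) length(unique(p)))
  n_per_evaluator <- setNames(as.vector(n_per_evaluator), as.character(labels))
  if (any(n_per_evaluator < 10)) {
    warn(sprintf("%d evaluator(s) have fewer than 10 participants; their effect estimates may be unstable.",
                 sum(n_per_evaluator < 10)))
  }

  frame <- data
  frame$.evqc_ev <- fct
  term_labels <- c(ev_terms <- ".evqc_ev",
                   if (!is.null(covariates)) attr(stats::terms(covariates), "term.labels"),
                   if (!is.null(measurement_covariates))
                     attr(stats::terms(measurement_covariates), "term.labels"))
  fml <- stats::as.formula(paste("~ 0 +", paste(term_labels, collapse = " + ")),
                           env = environment())
  D <- model.matrix(fml, data = frame)
  ev_block <- which(attr(D, "assign") == 1L)
  stopifnot(length(ev_block) == length(labels))
  colnames(D)[ev_block] <- paste0("evaluator:", labels)
  y <- data[[outcome]]

  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    dep <- colnames(D)[qrD$pivot[(qrD$rank + 1L):ncol(D)]]
    abort(paste0("Design matrix is rank deficient; offending column(s): ",
                 paste(dep, collapse = ", "),
                 ". A covariate may be confounded with the evaluator indicators."),
          class = "evalqc_singular_design_error")
  }

  t_i <- table(part)
  if (method == "ols") {
    if (any(t_i > 1L)) {
      abort("method = 'ols' requires exactly one measurement per participant; use method = 'gee' for repeated measurements.",
            class = "evalqc_validation_error")
    }
    theta <- qr.coef(qrD, y)
    resid <- y - drop(D %*% theta)
    df_res <- nrow(D) - ncol(D)
    sigma2 <- sum(resid^2) / df_res
    vcov_theta <- sigma2 * chol2inv(chol(crossprod(D)))
    dimnames(vcov_theta) <- list(colnames(D), colnames(D))
    gee <- NULL
    scale <- sigma2
    working_correlation <- NULL
    alpha <- NULL
  } else {
    k_idx <- if (!is.null(measurement_index)) data[[measurement_index]] else NULL
    gee <- gee_solve(y = y, X = D, cluster = part, k_index = k_idx,
                     corstr = working_correlation,
                     tol = control$tol %||% 1e-8,
                     maxit = control$maxit %||% 100L)
    theta <- setNames(gee$theta, colnames(D))
    vcov_theta <- gee$vcov
    dimnames(vcov_theta) <- list(colnames(D), colnames(D))
    scale <- gee$scale
    alpha <- gee$alpha
  }

  structure(
    list(theta = theta,
         vcov = vcov_theta,
         evaluator_labels = labels,
         ev_block = ev_block,
         n_per_evaluator = n_per_evaluator,
         method = method,
         working_correlation = working_correlation,
         scale = scale,
         alpha = alpha,
         converged = if (is.null(gee)) TRUE else gee$converged,
         n_iter = if (is.null(gee)) 0L else gee$n_iter,
         nobs = nrow(D),
         n_participants = length(t_i),
         df_residual = nrow(D) - ncol(D)),
    class = "evaluator_fit"
  )
}

#' @export
print.evaluator_fit <- function(x, ...) {
  cat(sprintf("<evaluator_fit> %s%s: %d evaluators, %d participants, %d measurements\n",
              toupper(x$method),
              if (!is.null(x$working_correlation))
                paste0(" (", x$working_correlation, ")") else "",
              length(x$evaluator_labels), x$n_participants, x$nobs))
  cat(sprintf("  residual scale (sigma^2): %.4g\n", x$scale))
  if (!is.null(x$alpha) && length(x$alpha)) {
    cat("  working correlation estimate:",
        paste(format(x$alpha, digits = 3), collapse = " "), "\n")
  }
  invisible(x)
}

#' @rdname fit_evaluators
#' @param x,object An `evaluator_fit`.
#' @param ... Unused.
#' @export
tidy.evaluator_fit <- function(x, ...) {
  se <- sqrt(diag(x$vcov))
  stat <- (x$theta / se)^2
  tibble::tibble(
    term = names(x$theta),
    estimate = unname(x$theta),
    std.error = unname(se),
    statistic = unname(stat),
    p.value = pchisq(unname(stat), df = 1, lower.tail = FALSE)
  )
}

#' @rdname fit_evaluators
#' @export
glance.evaluator_fit <- function(x, ...) {
  tibble::tibble(
    nobs = x$nobs,
    n.participants = x$n_participants,
    n.evaluators = length(x$evaluator_labels),
    sigma = sqrt(x$scale),
    method = x$method,
    working.correlation = x$working_correlation %||% NA_character_,
    n.iter = x$n_iter,
    converged = x$converged
  )
}

#' Extract the evaluator-effect block of a stage-one fit
#'
#' Slices \eqn{\hat\beta} (the M evaluator coefficients) and its covariance
#' sub-matrix \eqn{\hat\Sigma} out of the full coefficient vector.
#'
#' @param fit An `evaluator_fit` from [fit_evaluators()].
#' @return An object of class `evaluator_effects` with elements `beta`
#'   (named M-vector), `Sigma` (M x M), `evaluator_labels` and
#'   `n_per_evaluator`. [tidy()] gives a per-evaluator tibble.
#' @export
extract_effects <- function(fit) {
  stopifnot(inherits(fit, "evaluator_fit"))
  idx <- fit$ev_block
  want <- paste0("evaluator:", fit$evaluator_labels)
  if (!identical(names(fit$theta)[idx], want)) {
    abort("Evaluator labels do not match the fitted coefficient names.",
          class = "evalqc_label_error")
  }
  beta <- setNames(unname(fit$theta[idx]), as.character(fit$evaluator_labels))
  Sigma <- fit$vcov[idx, idx, drop = FALSE]
  dimnames(Sigma) <- list(names(beta), names(beta))
  structure(
    list(beta = beta, Sigma = Sigma,
         evaluator_labels = fit$evaluator_labels,
         n_per_evaluator = fit$n_per_evaluator),
    class = "evaluator_effects"
  )
}

#' @export
print.evaluator_effects <- function(x, ...) {
  cat(sprintf("<evaluator_effects> %d evaluators\n", length(x$beta)))
  print(tidy(x), ...)
  invisible(x)
}

#' @rdname extract_effects
#' @param x An `evaluator_effects` object.
#' @param ... Unused.
#' @export
tidy.evaluator_effects <- function(x, ...) {
  tibble::tibble(
    evaluator = as.character(x$evaluator_labels),
    estimate = unname(x$beta),
    std.error = sqrt(diag(x$Sigma)),
    n = unname(x$n_per_evaluator[as.character(x$evaluator_labels)])
  )
}
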