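#' Contrast of one evaluator against the mean effect
#'
#' Weight vector \eqn{L_j} with entry \eqn{(M-1)/M} in position *j* and
#' \eqn{-1/M} elsewhere, so that \eqn{L_j^T\beta = \beta_j - \bar\beta}.
#' Entries sum to zero, making the contrast invariant to a shared shift in
#' all evaluator effects.
#'
#' @param j Target evaluator position, `1 <= j <= M`.
#' @param M Number of evaluators, at least 2.
#' @return A numeric M-vector.
#' @export
#' @examples
#' untruncated_contrast(1, 3)  # c(2/3, -1/3, -1/3)
untruncated_contrast <- function(j, M) {
  if (M < 2) abort("A mean contrast needs at least 2 evaluators.",
                   class = "evalqc_domain_error")
  if (j < 1 || j > M || j != as.integer(j)) {
    abort("`j` must be an integer in 1..M.", class = "evalqc_domain_error")
  }
  L <- rep(-1 / M, M)
  L[j] <- (M - 1) / M
  L
}

#' Truncated (trimmed) mean of evaluator effects
#'
#' Mean of the order statistics \eqn{\beta_{([M\delta]+1)}, \ldots,
#' \beta_{(M-[M\delta])}}, where \eqn{[x]} is the integer part (floor).
#' Discarding the \eqn{[M\delta]} smallest and largest effects keeps
#' candidate outliers from contaminating the reference level.
#'
#' @param beta Numeric vector of effects.
#' @param delta Truncation fraction in `[0, 0.5)`; `0` gives the plain mean.
#' @return The truncated mean (scalar).
#' @export
#' @examples
#' truncated_mean(1:10, 0.1)  # 5.5: drops 1 value from each tail
truncated_mean <- function(beta, delta) {
  M <- length(beta)
  if (delta < 0 || delta >= 0.5) {
    abort("`delta` must be in [0, 0.5).", class = "evalqc_domain_error")
  }
  k <- floor(M * delta)
  if (M - 2 * k < 1) {
    abort(sprintf("Truncation removes everything: M = %d, [M * delta] = %d.", M, k),
          class = "evalqc_domain_error")
  }
  mean(sort(beta)[(k + 1):(M - k)])
}

# Index set S of evaluators whose effect ranks in the retained middle block.
# Ties broken by evaluator index (stable sort), so the set is deterministic.
truncation_set <- function(beta, delta) {
  M <- length(beta)
  k <- floor(M * delta)
  if (delta < 0 || delta >= 0.5 || M - 2 * k < 1) {
    abort("Invalid truncation: `delta` must be in [0, 0.5) and leave at least one effect.",
          class = "evalqc_domain_error")
  }
  sort(order(beta)[(k + 1):(M - k)])
}

#' Contrast of one evaluator against the truncated mean effect
#'
#' Implements \eqn{\beta_j - \bar\beta_{truncated}} as a single linear
#' contrast. Let S be the set of evaluators whose estimated effect ranks in
#' the retained middle block (size \eqn{|S| = M - 2[M\delta]}, ties broken by
#' evaluator index). The contrast places \eqn{-1/|S|} on each member of S,
#' zero elsewhere, then adds \eqn{+1} at position *j* — so
#' \eqn{L^T\hat\beta = \hat\beta_j - \bar{\hat\beta}_{truncated}} exactly,
#' whether or not *j* itself ranks inside the retained block. Entries sum to
#' zero. With `delta = 0` this reduces to [untruncated_contrast()].
#'
#' The ranking is taken from the supplied estimates and treated as fixed when
#' the contrast variance is formed later (selection variability ignored).
#'
#' @param j Target evaluator position.
#' @param delta Truncation fraction in `[0, 0.5)`.
#' @param beta Numeric M-vector of estimated effects supplying the ranks.
#' @return A numeric M-vector.
#' @export
truncated_contrast <- function(j, delta, beta) {
  M <- length(beta)
  if (j < 1 || j > M || j != as.integer(j)) {
    abort("`j` must be an integer in 1..M.", class = "evalqc_domain_error")
  }
  S <- truncation_set(beta, delta)
  L <- numeric(M)
  L[S] <- -1 / length(S)
  L[j] <- L[j] + 1
  L
}

# All M contrasts as rows, sharing one ranking per fit.
contrast_matrix <- function(beta, delta) {
  M <- length(beta)
  S <- truncation_set(beta, delta)
  base <- numeric(M)
  base[S] <- -1 / length(S)
  C <- matrix(base, nrow = M, ncol = M, byrow = TRUE)
  C[cbind(seq_len(M), seq_len(M))] <- C[cbind(seq_len(M), seq_len(M))] + 1
  C
}

#' Wald chi-square test of a single contrast
#'
#' Tests \eqn{H_0: L^T\beta = 0} with the statistic
#' \eqn{(L^T\hat\beta)^2 / (L^T\hat\Sigma L)}, referred to the chi-square
#' distribution with one degree of freedom.
#'
#' @param contrast Numeric M-vector of contrast weights.
#' @param effects An `evaluator_effects` object from [extract_effects()].
#' @return One-row tibble: `estimate` (\eqn{L^T\hat\beta}), `std.error`,
#'   `statistic`, `p.value`.
#' @export
wald_test <- function(contrast, effects) {
  stopifnot(inherits(effects, "evaluator_effects"))
  if (length(contrast) != length(effects$beta)) {
    abort("Contrast length must equal the number of evaluators.",
          class = "evalqc_domain_error")
  }
  est <- sum(contrast * effects$beta)
  v <- drop(crossprod(contrast, effects$Sigma %*% contrast))
  if (!is.finite(v) || v <= 0) {
    abort(sprintf("Degenerate contrast variance (L'Sigma L = %.3g).", v),
          class = "evalqc_degenerate_variance_error")
  }
  stat <- est^2 / v
  tibble::tibble(estimate = est, std.error = sqrt(v), statistic = stat,
                 p.value = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Wald tests of every evaluator against the (truncated) mean effect
#'
#' Builds the contrast \eqn{L_j} for each evaluator — against the plain mean
#' when `delta = 0`, against the `delta`-truncated mean otherwise, with one
#' shared ranking of the estimated effects — and computes the Wald chi-square
#' test of \eqn{H_{0,j}: L_j^T \beta = 0}.
#'
#' @param effects An `evaluator_effects` object (or an `evaluator_fit`, from
#'   which the effects are extracted).
#' @param delta Truncation fraction in `[0, 0.5)` (default 0, i.e. compare to
#'   the untruncated mean).
#' @return A tibble of class `evaluator_tests` with one row per evaluator:
#'   `evaluator`, `n`, `estimate` (departure from the reference mean, in
#'   outcome units), `std.error`, `statistic`, `p.value`. The contrast matrix
#'   and `delta` travel along as attributes for downstream calibration.
#' @export
evaluator_tests <- function(effects, delta = 0) {
  if (inherits(effects, "evaluator_fit")) effects <- extract_effects(effects)
  stopifnot(inherits(effects, "evaluator_effects"))
  M <- length(effects$beta)
  C <- if (delta == 0) {
    t(vapply(seq_len(M), untruncated_contrast, numeric(M), M = M))
  } else {
    contrast_matrix(effects$beta, delta)
  }
  est <- drop(C %*% effects$beta)
  v <- rowSums((C %*% effects$Sigma) * C)
  if (any(!is.finite(v) | v <= 0)) {
    abort("Degenerate contrast variance for at least one evaluator.",
          class = "evalqc_degenerate_variance_error")
  }
  stat <- est^2 / v
  out <- tibble::tibble(
    evaluator = as.character(effects$evaluator_labels),
    n = unname(effects$n_per_evaluator[as.character(effects$evaluator_labels)]),
    estimate = est,
    std.error = sqrt(v),
    statistic = stat,
    p.value = pchisq(stat, df = 1, lower.tail = FALSE)
  )
  attr(out, "delta") <- delta
  attr(out, "contrasts") <- C
  class(out) <- c("evaluator_tests", class(out))
  out
}
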