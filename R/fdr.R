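#' Estimate the false discovery rate of the calibrated tests
#'
#' Approximates the expected proportion of true-null rejections among all
#' rejections by
#' \deqn{\hat{Q} = \frac{\sum_j \alpha_j(\phi)}{\sum_j I(p_j < \alpha_j(\phi))},}
#' the expected number of false rejections over the observed number of
#' rejections. The approximation targets a large number of tests M with
#' rejections present; with no rejections the estimate is 0 by convention
#' (no discoveries, so no false discoveries). The raw ratio can exceed 1 when
#' \eqn{\sum_j \alpha_j} exceeds the rejection count; the returned value is
#' clipped to `[0, 1]` with the raw ratio kept in attribute `"raw"`.
#'
#' @param alphas Per-evaluator significance levels \eqn{\alpha_j}.
#' @param pvalues Per-evaluator p-values, aligned with `alphas`.
#' @return Estimated FDR in `[0, 1]`, with attribute `raw`.
#' @export
estimate_fdr <- function(alphas, pvalues) {
  if (length(alphas) != length(pvalues)) {
    abort("`alphas` and `pvalues` must be aligned vectors of equal length.",
          class = "evalqc_domain_error")
  }
  k <- sum(pvalues < alphas)
  if (k == 0L) {
    return(structure(0, raw = 0))
  }
  raw <- sum(alphas) / k
  structure(min(raw, 1), raw = raw)
}

# round-half-away-from-zero: the rejection-pruning rule rounds Q*k to the
# nearest integer, and base round() would go to even at .5
round_half_up <- function(x) floor(x + 0.5)

#' Prune the rejection set by the estimated FDR
#'
#' With k rejected hypotheses and estimated FDR \eqn{\hat{Q}}, about
#' \eqn{\hat{Q} k} of the rejections are expected to be false. This ad hoc
#' correction removes the \eqn{\hat{Q} k} (rounded to the nearest integer)
#' rejections with the **largest** p-values, keeping the
#' \eqn{k - \lceil \hat{Q} k \rfloor} strongest ones.
#'
#' @param tests A calibrated `evaluator_tests` tibble with `rejected`,
#'   `alpha` and `p.value` columns (see [calibrate_tests()]), or any data
#'   frame with those columns.
#' @param fdr Estimated FDR; defaults to `estimate_fdr(alpha, p.value)` on
#'   the table itself.
#' @return The table with a logical `rejected_adjusted` column added
#'   (always a subset of `rejected`), and attribute `fdr_estimate`.
#' @export
fdr_adjust <- function(tests, fdr = NULL) {
  stopifnot(all(c("rejected", "p.value") %in% names(tests)))
  if (is.null(fdr)) {
    stopifnot("alpha" %in% names(tests))
    fdr <- estimate_fdr(tests$alpha, tests$p.value)
  }
  k <- sum(tests$rejected)
  drop_n <- min(round_half_up(as.numeric(fdr) * k), k)
  rej_idx <- which(tests$rejected)
  keep <- rep(FALSE, nrow(tests))
  if (k - drop_n > 0) {
    ord <- rej_idx[order(tests$p.value[rej_idx])]
    keep[ord[seq_len(k - drop_n)]] <- TRUE
  }
  out <- tests
  out$rejected_adjusted <- keep
  attr(out, "fdr_estimate") <- fdr
  for (a in c("delta", "contrasts", "c", "power")) {
    if (!is.null(attr(tests, a))) attr(out, a) <- attr(tests, a)
  }
  out
}

#' Benjamini-Hochberg rejection
#'
#' Classical step-up procedure controlling the FDR at `alpha_level`: sort the
#' p-values ascending and reject the first k hypotheses, where k is the
#' largest index with \eqn{P_{(k)} \le (k/M)\,\alpha}. A useful alternative
#' to the calibrated procedure when the number of tests M is small.
#'
#' @param pvalues Numeric vector of p-values.
#' @param alpha_level FDR level in (0, 1).
#' @return Logical vector aligned with `pvalues` (`TRUE` = rejected), with
#'   attribute `k`, the number of rejections.
#' @export
bh_reject <- function(pvalues, alpha_level) {
  if (alpha_level <= 0 || alpha_level >= 1) {
    abort("`alpha_level` must be in (0, 1).", class = "evalqc_domain_error")
  }
  M <- length(pvalues)
  ord <- order(pvalues)
  thresh <- seq_len(M) / M * alpha_level
  below <- pvalues[ord] <= thresh
  k <- if (any(below)) max(which(below)) else 0L
  rejected <- rep(FALSE, M)
  if (k > 0L) rejected[ord[seq_len(k)]] <- TRUE
  structure(rejected, k = k)
}
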