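#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a decision curve
#'
#' Estimated FDR against target power — the plot used to pick an operating
#' point. Raw grid points joined by lines; no smoothing is applied.
#'
#' @param object A `decision_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.decision_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$power, y = .data$fdr_estimate)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "Target power φ", y = "Estimated FDR",
                  title = "FDR vs power decision curve") +
    ggplot2::theme_minimal()
}

#' Plot per-evaluator departures from the reference mean
#'
#' Each evaluator's estimated departure \eqn{L_j^T\hat\beta} from the
#' (truncated) mean effect with a pointwise 95% interval; flagged evaluators
#' are highlighted when the table carries rejection columns.
#'
#' @param object An `evaluator_tests` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.evaluator_tests <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d$flag <- if ("rejected_adjusted" %in% names(d)) {
    factor(ifelse(d$rejected_adjusted, "flagged (FDR-pruned)",
                  ifelse(d$rejected, "flagged", "not flagged")),
           levels = c("not flagged", "flagged", "flagged (FDR-pruned)"))
  } else if ("rejected" %in% names(d)) {
    factor(ifelse(d$rejected, "flagged", "not flagged"),
           levels = c("not flagged", "flagged"))
  } else {
    factor("not flagged")
  }
  d$evaluator <- factor(d$evaluator, levels = d$evaluator)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$evaluator, y = .data$estimate,
                                  colour = .data$flag)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$estimate - 1.96 * .data$std.error,
      ymax = .data$estimate + 1.96 * .data$std.error), size = 0.2) +
    ggplot2::labs(x = "Evaluator", y = "Departure from reference mean",
                  colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5,
                                                       size = 6))
}

#' Plot simulated operating characteristics
#'
#' Mean estimated FDR and mean empirical false-discovery proportion against
#' target power, with the fixed-level baseline as a horizontal reference —
#' showing how well the FDR estimator tracks the truth under the design.
#'
#' @param object A `study_summary` from [replicate_study()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.study_summary <- function(object, ...) {
  d <- tidyr::pivot_longer(object$curve,
                           c("fdr_estimated", "fdr_empirical"),
                           names_to = "which", values_to = "fdr")
  d$which <- factor(d$which, levels = c("fdr_estimated", "fdr_empirical"),
                    labels = c("estimated", "empirical"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$power, y = .data$fdr,
                                  linetype = .data$which)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$fixed_fdp, linetype = "dotdash",
                        colour = "grey40") +
    ggplot2::labs(x = "Target power φ", y = "FDR", linetype = NULL,
                  title = sprintf("Operating characteristics (sigma = %g, %d replicates)",
                                  object$design$sigma, object$n_replicates)) +
    ggplot2::theme_minimal()
}
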