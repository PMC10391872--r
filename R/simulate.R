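#' Simulation design for multi-evaluator audiometric data
#'
#' Describes the generating model
#' \deqn{Y_i = \gamma_1 age_i + \gamma_2 age_i^2 + \gamma_3 I(very\,good_i)
#'   + \gamma_4 I(little\,trouble_i) + \beta_{j(i)} + \epsilon_i,
#'   \quad \epsilon_i \sim N(0, \sigma^2),}
#' emulating right-ear hearing-threshold measurements (dB HL) collected by M
#' audiologists. The defaults are the study conditions used throughout the
#' package's operating-characteristic simulations: M = 100 evaluators with 40
#' participants each, age normal with mean 56.6 and SD 4.4 years,
#' self-reported hearing status 'excellent' (reference) / 'very good'
#' (prevalence 0.44) / 'a little hearing trouble' (0.25), covariate
#' coefficients (-2.7, 0.03, 3.3, 10.3), and true evaluator effects 75 for
#' evaluators 1-5, 70 for 6-8 and 67 for the remaining 92 — so the 10%
#' truncated mean of the true effects is 67 and evaluators 1-8 are the true
#' outliers. The optional bilateral variant gives every participant two
#' measurements (ears) sharing the mean structure, with bivariate normal
#' residuals of correlation `rho`.
#'
#' @param M Number of evaluators.
#' @param n_per_evaluator Participants per evaluator (scalar or length-M).
#' @param gamma Coefficients for age, age^2, I(very good), I(little trouble).
#' @param beta True evaluator effects (length M), in outcome units.
#' @param sigma Residual SD (the study conditions consider 8, 10 and 12).
#' @param age_mean,age_sd Age distribution parameters (years).
#' @param prevalences Named probabilities of the two non-reference hearing
#'   status categories; the reference 'excellent' takes the remainder.
#' @param bilateral Generate two correlated measurements per participant?
#' @param rho Within-participant residual correlation for the bilateral
#'   variant (default 0.7, as observed between left/right ear thresholds).
#' @return An object of class `sim_design`. True outliers (element
#'   `true_outlier`) are the evaluators whose effect differs from the 10%
#'   truncated mean of the true effects.
#' @export
sim_design <- function(M = 100,
                       n_per_evaluator = 40,
                       gamma = c(-2.7, 0.03, 3.3, 10.3),
                       beta = c(rep(75, 5), rep(70, 3), rep(67, 92)),
                       sigma = 8,
                       age_mean = 56.6, age_sd = 4.4,
                       prevalences = c(very_good = 0.44, little_trouble = 0.25),
                       bilateral = FALSE,
                       rho = 0.7) {
  if (length(beta) != M) abort("`beta` must have length M.", class = "evalqc_domain_error")
  if (length(n_per_evaluator) == 1L) n_per_evaluator <- rep(n_per_evaluator, M)
  if (length(n_per_evaluator) != M || any(n_per_evaluator < 1)) {
    abort("`n_per_evaluator` must be a positive scalar or length-M vector.",
          class = "evalqc_domain_error")
  }
  if (length(gamma) != 4) abort("`gamma` must have length 4.", class = "evalqc_domain_error")
  if (sigma <= 0) abort("`sigma` must be > 0.", class = "evalqc_domain_error")
  if (any(prevalences < 0) || sum(prevalences) > 1) {
    abort("`prevalences` must be in [0,1] with sum <= 1 (reference takes the rest).",
          class = "evalqc_domain_error")
  }
  if (abs(rho) >= 1) abort("`rho` must satisfy |rho| < 1.", class = "evalqc_domain_error")
  ref <- truncated_mean(beta, 0.1)
  structure(
    list(M = M, n_per_evaluator = n_per_evaluator, gamma = gamma, beta = beta,
         sigma = sigma, age_mean = age_mean, age_sd = age_sd,
         prevalences = prevalences, bilateral = bilateral, rho = rho,
         true_outlier = beta != ref),
    class = "sim_design"
  )
}

#' @export
print.sim_design <- function(x, ...) {
  cat(sprintf("<sim_design> M = %d evaluators, N = %d participants, sigma = %g%s\n",
              x$M, sum(x$n_per_evaluator), x$sigma,
              if (x$bilateral) sprintf(", bilateral (rho = %g)", x$rho) else ""))
  cat(sprintf("  true outliers: %d of %d\n", sum(x$true_outlier), x$M))
  invisible(x)
}

#' Generate one measurement table from a simulation design
#'
#' Participants are allocated to evaluators in consecutive blocks
#' (participants 1..n_1 to evaluator 1, and so on); effects are exchangeable
#' and covariates independent of assignment, so the allocation scheme is
#' immaterial. With `design$bilateral` each participant contributes two rows
#' (`measurement_index` 1 and 2, `ear` left/right) whose residuals are
#' bivariate normal with correlation `design$rho`.
#'
#' @param design A [sim_design()].
#' @param seed Optional integer seed (set for reproducibility; `NULL` leaves
#'   the RNG state alone).
#' @return A tibble with columns `participant_id`, `evaluator_id`, `age`,
#'   `hearing_status` (factor, reference 'excellent'), `outcome`, and for
#'   bilateral designs `measurement_index` and `ear`.
#' @export
simulate_measurements <- function(design, seed = NULL) {
  stopifnot(inherits(design, "sim_design"))
  if (!is.null(seed)) set.seed(seed)
  N <- sum(design$n_per_evaluator)
  ev <- rep(seq_len(design$M), times = design$n_per_evaluator)
  age <- rnorm(N, design$age_mean, design$age_sd)
  p_ref <- 1 - sum(design$prevalences)
  status <- sample(c("excellent", "very_good", "little_trouble"), N,
                   replace = TRUE, prob = c(p_ref, design$prevalences[["very_good"]],
                                            design$prevalences[["little_trouble"]]))
  status <- factor(status, levels = c("excellent", "very_good", "little_trouble"))
  g <- design$gamma
  mu <- g[1] * age + g[2] * age^2 + g[3] * (status == "very_good") +
    g[4] * (status == "little_trouble") + design$beta[ev]

  if (!design$bilateral) {
    return(tibble::tibble(
      participant_id = seq_len(N),
      evaluator_id = ev,
      age = age,
      hearing_status = status,
      outcome = mu + rnorm(N, 0, design$sigma)
    ))
  }
  # bivariate normal residuals with exchangeable correlation rho:
  # e2 = rho * e1 + sqrt(1 - rho^2) * z keeps both margins N(0, sigma^2)
  e1 <- rnorm(N, 0, design$sigma)
  e2 <- design$rho * e1 + sqrt(1 - design$rho^2) * rnorm(N, 0, design$sigma)
  tibble::tibble(
    participant_id = rep(seq_len(N), each = 2L),
    measurement_index = rep(1:2, N),
    ear = rep(c("right", "left"), N),
    evaluator_id = rep(ev, each = 2L),
    age = rep(age, each = 2L),
    hearing_status = rep(status, each = 2L),
    outcome = rep(mu, each = 2L) + as.vector(rbind(e1, e2))
  )
}

#' Operating characteristics of the procedure over simulation replicates
#'
#' Repeatedly generates data from `design`, runs the two-stage procedure
#' (stage-one fit, `delta`-truncated contrasts, Wald tests), calibrates the
#' evaluator-specific levels at every power on `power_grid` against the
#' alternative \eqn{|L^T\beta| = c}, and records — per power — the estimated
#' FDR, the per-replicate empirical false-discovery proportion (falsely
#' flagged true-normal evaluators over all flagged; 0/0 counts as 0), the
#' same after FDR-based pruning, and per-evaluator detection proportions.
#' A conventional fixed-level baseline (`fixed_alpha`, default 0.05) is
#' recorded alongside.
#'
#' One master seed spawns an independent per-replicate seed stream, so any
#' replicate can be regenerated in isolation.
#'
#' @param design A [sim_design()].
#' @param n_replicates Number of simulation replicates.
#' @param power_grid Powers at which to calibrate.
#' @param c Alternative magnitude.
#' @param delta Truncation fraction for the reference mean.
#' @param seed Master seed.
#' @param fixed_alpha Fixed significance level for the baseline comparison.
#' @return An object of class `study_summary`: tibbles `curve` (per power:
#'   mean estimated FDR, mean empirical FDP unadjusted and adjusted, mean
#'   rejections), `evaluators` (per power x evaluator: detection
#'   proportions, unadjusted and adjusted), `fixed` (per evaluator: detection
#'   proportion at the fixed level) and scalars `fixed_fdp` (mean empirical
#'   FDP at the fixed level) plus the design and replicate count.
#' @export
replicate_study <- function(design,
                            n_replicates = 300,
                            power_grid = seq(0.10, 0.95, by = 0.01),
                            c = 5,
                            delta = 0.1,
                            seed = NULL,
                            fixed_alpha = 0.05) {
  stopifnot(inherits(design, "sim_design"), n_replicates >= 1)
  if (!is.null(seed)) set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_replicates)
  M <- design$M
  G <- length(power_grid)
  normal <- !design$true_outlier

  fdp <- matrix(NA_real_, n_replicates, G)
  fdp_adj <- matrix(NA_real_, n_replicates, G)
  qhat <- matrix(NA_real_, n_replicates, G)
  nrej <- matrix(NA_real_, n_replicates, G)
  det_un <- array(0, c(M, G))     # detection counts, unadjusted
  det_adj <- array(0, c(M, G))
  det_fixed <- numeric(M)
  fdp_fixed <- numeric(n_replicates)

  covars <- ~ age + I(age^2) + hearing_status
  for (r in seq_len(n_replicates)) {
    tab <- simulate_measurements(design, seed = rep_seeds[r])
    fit <- if (design$bilateral) {
      fit_evaluators(tab, covariates = covars, method = "gee",
                     working_correlation = "exchangeable",
                     measurement_index = "measurement_index")
    } else {
      fit_evaluators(tab, covariates = covars, method = "ols")
    }
    tests <- evaluator_tests(extract_effects(fit), delta = delta)
    lambda <- c^2 / tests$std.error^2
    p <- tests$p.value

    for (g in seq_len(G)) {
      alpha <- alpha_for_power(lambda, power_grid[g])
      rej <- p < alpha
      k <- sum(rej)
      nrej[r, g] <- k
      qg <- as.numeric(estimate_fdr(alpha, p))
      qhat[r, g] <- qg
      fdp[r, g] <- if (k == 0) 0 else sum(rej & normal) / k
      det_un[, g] <- det_un[, g] + rej
      # FDR-based pruning of the largest-p rejections
      drop_n <- min(round_half_up(qg * k), k)
      keep <- logical(M)
      if (k - drop_n > 0) {
        ord <- which(rej)[order(p[rej])]
        keep[ord[seq_len(k - drop_n)]] <- TRUE
      }
      ka <- sum(keep)
      fdp_adj[r, g] <- if (ka == 0) 0 else sum(keep & normal) / ka
      det_adj[, g] <- det_adj[, g] + keep
    }
    rej_f <- p < fixed_alpha
    det_fixed <- det_fixed + rej_f
    kf <- sum(rej_f)
    fdp_fixed[r] <- if (kf == 0) 0 else sum(rej_f & normal) / kf
  }

  curve <- tibble::tibble(
    power = power_grid,
    fdr_estimated = colMeans(qhat),
    fdr_empirical = colMeans(fdp),
    fdr_empirical_adjusted = colMeans(fdp_adj),
    mean_rejections = colMeans(nrej)
  )
  evaluators <- tidyr::expand_grid(power = power_grid,
                                   evaluator = seq_len(M)) |>
    dplyr::arrange(.data$power, .data$evaluator)
  evaluators$true_outlier <- rep(design$true_outlier, times = G)
  evaluators$prop_detected <- as.vector(det_un) / n_replicates
  evaluators$prop_detected_adjusted <- as.vector(det_adj) / n_replicates

  structure(
    list(curve = curve,
         evaluators = evaluators,
         fixed = tibble::tibble(evaluator = seq_len(M),
                                true_outlier = design$true_outlier,
                                prop_detected = det_fixed / n_replicates),
         fixed_fdp = mean(fdp_fixed),
         fixed_alpha = fixed_alpha,
         n_replicates = n_replicates,
         c = c, delta = delta,
         design = design),
    class = "study_summary"
  )
}

#' @export
print.study_summary <- function(x, ...) {
  cat(sprintf("<study_summary> %d replicates, M = %d, sigma = %g\n",
              x$n_replicates, x$design$M, x$design$sigma))
  top <- x$curve[which.max(x$curve$power), ]
  cat(sprintf("  at power %.2f: estimated FDR %.3f, empirical FDP %.3f\n",
              top$power, top$fdr_estimated, top$fdr_empirical))
  cat(sprintf("  fixed alpha = %g baseline: empirical FDP %.3f\n",
              x$fixed_alpha, x$fixed_fdp))
  invisible(x)
}
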