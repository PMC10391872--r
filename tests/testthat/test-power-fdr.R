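test_that("power at a given level matches the normal-theory oracle", {
  # under the null the power equals the significance level
  expect_equal(power_at_alpha(0, 0.05), 0.05, tolerance = 1e-12)
  expect_equal(power_at_alpha(0, 0.2), 0.2, tolerance = 1e-12)
  # two-sided z-test oracle: Phi(sqrt(l) - z_{1-a/2}) + Phi(-sqrt(l) - z_{1-a/2})
  z_oracle <- function(lambda, alpha) {
    za <- qnorm(1 - alpha / 2)
    pnorm(sqrt(lambda) - za) + pnorm(-sqrt(lambda) - za)
  }
  for (lam in c(1, 5, 10.507, 30)) {
    expect_equal(power_at_alpha(lam, 0.05), z_oracle(lam, 0.05), tolerance = 1e-9)
  }
  expect_equal(power_at_alpha(10.507, 0.05), 0.90, tolerance = 1e-3)
  # strictly increasing in lambda at fixed alpha
  grid <- power_at_alpha(seq(0, 40, by = 2), 0.05)
  expect_true(all(diff(grid) > 0))
  expect_error(power_at_alpha(-1, 0.05), class = "evalqc_domain_error")
  expect_error(power_at_alpha(1, 1.5), class = "evalqc_domain_error")
})

test_that("level-for-power inverts the power formula", {
  for (lam in c(0.5, 2, 10.507, 25, 80)) {
    for (phi in c(0.1, 0.5, 0.9, 0.99)) {
      a <- alpha_for_power(lam, phi)
      expect_lt(abs(power_at_alpha(lam, a) - phi), 1e-8)
    }
  }
  expect_equal(alpha_for_power(10.507, 0.90), 0.05, tolerance = 1e-3)
  # alpha increasing in phi, decreasing in lambda
  a_phi <- alpha_for_power(10, seq(0.1, 0.9, by = 0.1))
  expect_true(all(diff(a_phi) > 0))
  a_lam <- alpha_for_power(c(2, 5, 10, 20, 100), 0.8)
  expect_true(all(diff(a_lam) < 0))
  expect_lt(alpha_for_power(1e4, 0.8), 1e-15)
  expect_error(alpha_for_power(0, 0.8), class = "evalqc_domain_error")
})

test_that("noncentrality is c^2 over the contrast variance", {
  eye2 <- diag(2)
  expect_equal(noncentrality(c(1, 0), eye2, 5), 25)
  expect_equal(noncentrality(c(1, 0), 25 * eye2, 5), 1)
  expect_equal(noncentrality(c(1, 0), eye2, 10), 4 * noncentrality(c(1, 0), eye2, 5))
  expect_error(noncentrality(c(0, 0), eye2, 5),
               class = "evalqc_degenerate_variance_error")
})

test_that("the FDR estimator is the expected-false over observed rejections", {
  alphas <- rep(0.05, 100)
  p <- c(rep(0.001, 10), rep(0.5, 90))
  expect_equal(as.numeric(estimate_fdr(alphas, p)), 0.5)  # 5 / 10
  # everything rejected -> mean alpha
  expect_equal(as.numeric(estimate_fdr(alphas, rep(0.001, 100))), 0.05)
  # no rejections -> 0 by convention
  expect_identical(as.numeric(estimate_fdr(alphas, rep(0.9, 100))), 0)
  # clipped at 1, raw ratio preserved
  est <- estimate_fdr(rep(0.5, 10), c(0.01, rep(0.9, 9)))
  expect_identical(as.numeric(est), 1)
  expect_equal(attr(est, "raw"), 5)
  # monotone in the alphas holding the rejection count fixed
  expect_lt(as.numeric(estimate_fdr(rep(0.02, 100), p)),
            as.numeric(estimate_fdr(rep(0.05, 100), p)))
})

test_that("FDR pruning removes the round(Q*k) largest p-value rejections", {
  mk <- function(p, rejected) tibble::tibble(p.value = p, rejected = rejected)
  # k = 12, Q = 0.28 -> drop round(3.36) = 3, keep 9
  t12 <- mk(seq(0.001, 0.012, by = 0.001), rep(TRUE, 12))
  out <- fdr_adjust(t12, fdr = 0.28)
  expect_identical(sum(out$rejected_adjusted), 9L)
  expect_identical(which(out$rejected_adjusted), 1:9)
  # Q = 0 keeps everything, Q = 1 keeps nothing
  expect_identical(sum(fdr_adjust(mk(1:5 / 100, rep(TRUE, 5)), fdr = 0)$rejected_adjusted), 5L)
  expect_identical(sum(fdr_adjust(mk(1:4 / 100, rep(TRUE, 4)), fdr = 1)$rejected_adjusted), 0L)
  # rounding is half-away-from-zero: Q*k = 2.5 -> drop 3
  out <- fdr_adjust(mk(1:10 / 100, rep(TRUE, 10)), fdr = 0.25)
  expect_identical(sum(out$rejected_adjusted), 7L)
  # never keeps a larger p while dropping a smaller one
  set.seed(4)
  for (r in 1:20) {
    p <- runif(15)
    rej <- p < 0.6
    out <- fdr_adjust(mk(p, rej), fdr = runif(1))
    kept <- p[out$rejected_adjusted]
    dropped <- p[rej & !out$rejected_adjusted]
    if (length(kept) && length(dropped)) expect_lt(max(kept), min(dropped))
    expect_true(all(out$rejected_adjusted <= rej))
  }
})

test_that("Benjamini-Hochberg matches an exhaustive-k oracle", {
  rej <- bh_reject(c(0.01, 0.02, 0.5), 0.1)
  expect_identical(which(rej), 1:2)
  expect_identical(attr(rej, "k"), 2L)
  expect_identical(sum(bh_reject(c(0.5, 0.6, 0.9), 0.1)), 0L)
  set.seed(14)
  for (r in 1:40) {
    M <- sample(1:20, 1)
    p <- round(runif(M), 2)  # ties included
    a <- runif(1, 0.01, 0.3)
    expect_identical(which(bh_reject(p, a)), which(bh_oracle(p, a)))
  }
})
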