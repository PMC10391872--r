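# Shared fixtures and independent oracles for the test suite.

# tiny single-measurement table: evaluator A -> outcomes {1,3}, B -> {5,7}
toy_table <- function() {
  tibble::tibble(
    participant_id = 1:4,
    evaluator_id = c("A", "A", "B", "B"),
    outcome = c(1, 3, 5, 7)
  )
}

# random single-measurement table with continuous covariates
random_table <- function(n_per = 10, M = 3, p = 2, sigma = 1, seed = 1) {
  set.seed(seed)
  N <- n_per * M
  X <- matrix(rnorm(N * p), N, p, dimnames = list(NULL, paste0("x", seq_len(p))))
  ev <- rep(seq_len(M), each = n_per)
  beta <- seq(10, 10 + M - 1)
  gamma <- seq_len(p)
  tibble::tibble(
    participant_id = seq_len(N),
    evaluator_id = ev,
    outcome = drop(X %*% gamma) + beta[ev] + rnorm(N, 0, sigma)
  ) |> dplyr::bind_cols(tibble::as_tibble(X))
}

# normal-equations oracle: theta = (D'D)^{-1} D'y, vcov = s2 (D'D)^{-1}
ols_oracle <- function(D, y) {
  DtD_inv <- solve(t(D) %*% D)
  theta <- drop(DtD_inv %*% t(D) %*% y)
  r <- y - drop(D %*% theta)
  s2 <- sum(r^2) / (length(y) - ncol(D))
  list(theta = theta, vcov = s2 * DtD_inv, sigma2 = s2)
}

# exhaustive-k Benjamini-Hochberg oracle
bh_oracle <- function(p, alpha) {
  M <- length(p)
  ps <- sort(p)
  k_best <- 0L
  for (k in seq_len(M)) if (ps[k] <= k / M * alpha) k_best <- k
  rejected <- rep(FALSE, M)
  if (k_best > 0) rejected[order(p)[seq_len(k_best)]] <- TRUE
  rejected
}

# brute-force truncated mean: sort, drop floor(M*delta) from each tail
trunc_mean_oracle <- function(beta, delta) {
  k <- floor(length(beta) * delta)
  b <- sort(beta)
  mean(b[(k + 1):(length(b) - k)])
}

# small simulation design used where full scale is unnecessary
tiny_design <- function(sigma = 4, M = 12, n = 25,
                        beta = c(rep(75, 2), rep(67, 10)), ...) {
  sim_design(M = M, n_per_evaluator = n, beta = beta, sigma = sigma, ...)
}
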