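# Gaussian identity-link GEE solver with robust sandwich covariance.
# Clusters are participants; the working variance is scale * R(alpha) with
# R independent, exchangeable or unstructured. With identity link the update
# is a single weighted least-squares solve, iterated because R depends on the
# residuals through the moment estimators of alpha and the scale.

gee_solve <- function(y, X, cluster, k_index = NULL,
                      corstr = c("independent", "exchangeable", "unstructured"),
                      tol = 1e-8, maxit = 100L) {
  corstr <- match.arg(corstr)
  q <- ncol(X)
  cl <- split(seq_along(y), factor(cluster, levels = unique(cluster)))
  t_i <- lengths(cl)
  t_max <- max(t_i)

  # measurement position within cluster, 1..t_i (needed for unstructured)
  pos <- integer(length(y))
  for (idx in cl) {
    k <- if (is.null(k_index)) seq_along(idx) else rank(k_index[idx], ties.method = "first")
    pos[idx] <- k
  }
  if (corstr == "unstructured" && t_max > 1L) {
    n_pairs <- outer(seq_len(t_max), seq_len(t_max), Vectorize(function(a, b) {
      sum(vapply(cl, function(idx) all(c(a, b) %in% pos[idx]), logical(1)))
    }))
    off <- n_pairs[upper.tri(n_pairs)]
    if (any(off - q < 1)) {
      abort(sprintf("Too few clusters (minimum shared pairs %d, need > %d model parameters) to estimate the unstructured correlation.",
                    min(off), q),
            class = "evalqc_estimation_error")
    }
  }

  theta <- qr.coef(qr(X), y)  # OLS start
  alpha <- NULL
  R_corr <- diag(1, t_max)
  converged <- FALSE
  n_iter <- 0L
  rel_change <- NA_real_

  for (iter in seq_len(maxit)) {
    n_iter <- iter
    r <- y - drop(X %*% theta)
    scale <- sum(r^2) / (length(y) - q)
    e <- r / sqrt(scale)

    if (corstr == "exchangeable" && t_max > 1L) {
      num <- 0; npair <- 0
      for (idx in cl) {
        ti <- length(idx)
        if (ti > 1L) {
          s <- sum(e[idx])
          num <- num + (s^2 - sum(e[idx]^2)) / 2
          npair <- npair + ti * (ti - 1) / 2
        }
      }
      denom <- max(npair - q, 1)
      a <- num / denom
      lo <- -1 / (t_max - 1) + 1e-6
      a <- min(max(a, lo), 1 - 1e-6)
      alpha <- c(alpha = a)
      R_corr <- matrix(a, t_max, t_max); diag(R_corr) <- 1
    } else if (corstr == "unstructured" && t_max > 1L) {
      S <- matrix(0, t_max, t_max); cnt <- matrix(0, t_max, t_max)
      for (idx in cl) {
        p <- pos[idx]
        S[p, p] <- S[p, p] + tcrossprod(e[idx])
        cnt[p, p] <- cnt[p, p] + 1
      }
      R_corr <- S / pmax(cnt - q, 1)
      diag(R_corr) <- 1
      R_corr <- (R_corr + t(R_corr)) / 2
      off <- R_corr[upper.tri(R_corr)]
      R_corr[upper.tri(R_corr)] <- pmin(pmax(off, -1 + 1e-6), 1 - 1e-6)
      R_corr[lower.tri(R_corr)] <- t(R_corr)[lower.tri(R_corr)]
      alpha <- R_corr[upper.tri(R_corr)]
    }

    # Rinv for each cluster size / position pattern
    A <- matrix(0, q, q); b <- numeric(q)
    for (idx in cl) {
      p <- pos[idx]
      Ri <- R_corr[p, p, drop = FALSE]
      Rinv <- if (length(idx) == 1L) matrix(1 / Ri, 1, 1) else chol2inv(chol(Ri))
      Xi <- X[idx, , drop = FALSE]
      W <- crossprod(Xi, Rinv)
      A <- A + W %*% Xi
      b <- b + drop(W %*% y[idx])
    }
    theta_new <- solve(A, b)
    rel_change <- max(abs(theta_new - theta)) / max(1, max(abs(theta_new)))
    theta <- theta_new
    if (rel_change < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    abort(sprintf("GEE did not converge in %d iterations (last relative update %.3g).",
                  maxit, rel_change),
          class = "evalqc_convergence_error")
  }

  # sandwich: A^{-1} (sum_i Xi' Vi^{-1} ri ri' Vi^{-1} Xi) A^{-1},
  # with Vi = scale * R; the scale enters A and the meat consistently.
  r <- y - drop(X %*% theta)
  scale <- sum(r^2) / (length(y) - q)
  A <- matrix(0, q, q); meat <- matrix(0, q, q)
  for (idx in cl) {
    p <- pos[idx]
    Ri <- R_corr[p, p, drop = FALSE]
    Rinv <- if (length(idx) == 1L) matrix(1 / Ri, 1, 1) else chol2inv(chol(Ri))
    Vinv <- Rinv / scale
    Xi <- X[idx, , drop = FALSE]
    W <- crossprod(Xi, Vinv)
    A <- A + W %*% Xi
    u <- drop(W %*% r[idx])
    meat <- meat + tcrossprod(u)
  }
  Ainv <- solve(A)
  vcov <- Ainv %*% meat %*% Ainv
  vcov <- (vcov + t(vcov)) / 2

  list(theta = theta, vcov = vcov, scale = scale,
       alpha = alpha, converged = converged, n_iter = n_iter)
}
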