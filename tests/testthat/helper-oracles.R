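# Independent oracles used by the tests: dense quadrature for mixture
# posteriors, brute-force marginal likelihood for tiny models, and the
# closed-form ridge solution.  These never call the package's own solvers.

log_dmvnorm <- function(x, mean, Sigma) {
  L <- chol(Sigma)
  z <- backsolve(L, x - mean, transpose = TRUE)
  -0.5 * (length(x) * log(2 * pi) + 2 * sum(log(diag(L))) + sum(z^2))
}

# Vectorized normal density of rows of X under N(mean, Sigma).
log_dmvnorm_rows <- function(X, mean, Sigma) {
  L <- chol(Sigma)
  Z <- backsolve(L, t(X) - mean, transpose = TRUE)
  -0.5 * (ncol(X) * log(2 * pi) + 2 * sum(log(diag(L))) + colSums(Z^2))
}

# Posterior moments of b with prior sum_k w0_k N(0, S0_k) and likelihood
# N(bhat; b, S), by dense quadrature.  Rank-deficient components are
# integrated over their eigen-subspace; the null component is a point mass
# at zero.  Returns responsibilities, blended mean and second moment.
quadrature_posterior <- function(bhat, S, S0_list, w0, ngrid = 601,
                                 width = 10) {
  r <- length(bhat)
  K <- length(S0_list)
  Zk <- numeric(K)
  meank <- matrix(0, r, K)
  M2k <- array(0, c(r, r, K))
  for (k in seq_len(K)) {
    S0 <- S0_list[[k]]
    ee <- eigen(S0, symmetric = TRUE)
    pos <- which(ee$values > 1e-12 * max(ee$values, 1))
    d <- length(pos)
    if (d == 0) {                       # point mass at zero
      Zk[k] <- exp(log_dmvnorm(bhat, rep(0, r), S))
      next
    }
    U <- ee$vectors[, pos, drop = FALSE]
    lam <- ee$values[pos]
    lims <- width * sqrt(lam + max(diag(S)))
    grids <- lapply(seq_len(d), function(l)
      seq(-lims[l], lims[l], length.out = ngrid))
    G <- as.matrix(expand.grid(grids))
    Bpts <- G %*% t(U)                  # points in effect space
    lp <- rep(0, nrow(G))
    for (l in seq_len(d))
      lp <- lp + dnorm(G[, l], 0, sqrt(lam[l]), log = TRUE)
    lp <- lp + log_dmvnorm_rows(Bpts, bhat, S)
    wq <- prod(vapply(grids, function(g) g[2] - g[1], numeric(1)))
    f <- exp(lp)
    Zk[k] <- sum(f) * wq
    meank[, k] <- colSums(Bpts * f) * wq / Zk[k]
    M2k[, , k] <- crossprod(Bpts, Bpts * f) * wq / Zk[k]
  }
  w1 <- w0 * Zk
  w1 <- w1 / sum(w1)
  mean_b <- as.vector(meank %*% w1)
  M2 <- matrix(0, r, r)
  for (k in seq_len(K)) M2 <- M2 + w1[k] * M2k[, , k]
  list(w1 = w1, mean = mean_b, second_moment = M2)
}

# Exact log marginal likelihood of y ~ N(X b, tau2 I) with independent
# mixture priors b_j ~ sum_k w0_k N(0, s_k) for p = 2, r = 1, by
# enumerating component assignments and 2-D quadrature over (b1, b2).
exact_logml_p2 <- function(X, y, s0, w0, tau2, ngrid = 2001, width = 10) {
  stopifnot(ncol(X) == 2)
  n <- length(y)
  K <- length(s0)
  loglik_b <- function(b1, b2) {
    resid2 <- colSums((y - outer(X[, 1], b1) - outer(X[, 2], b2))^2)
    -0.5 * (n * log(2 * pi * tau2) + resid2 / tau2)
  }
  comp_int <- matrix(NA_real_, K, K)
  for (k1 in seq_len(K)) {
    for (k2 in seq_len(K)) {
      if (s0[k1] == 0 && s0[k2] == 0) {
        li <- loglik_b(0, 0)
      } else if (s0[k1] == 0) {
        g <- seq(-width * sqrt(s0[k2]), width * sqrt(s0[k2]),
                 length.out = ngrid)
        lp <- loglik_b(rep(0, ngrid), g) + dnorm(g, 0, sqrt(s0[k2]),
                                                 log = TRUE)
        m <- max(lp)
        li <- m + log(sum(exp(lp - m)) * (g[2] - g[1]))
      } else if (s0[k2] == 0) {
        g <- seq(-width * sqrt(s0[k1]), width * sqrt(s0[k1]),
                 length.out = ngrid)
        lp <- loglik_b(g, rep(0, ngrid)) + dnorm(g, 0, sqrt(s0[k1]),
                                                 log = TRUE)
        m <- max(lp)
        li <- m + log(sum(exp(lp - m)) * (g[2] - g[1]))
      } else {
        g1 <- seq(-width * sqrt(s0[k1]), width * sqrt(s0[k1]),
                  length.out = ngrid)
        g2 <- seq(-width * sqrt(s0[k2]), width * sqrt(s0[k2]),
                  length.out = ngrid)
        G <- expand.grid(b1 = g1, b2 = g2)
        lp <- loglik_b(G$b1, G$b2) +
          dnorm(G$b1, 0, sqrt(s0[k1]), log = TRUE) +
          dnorm(G$b2, 0, sqrt(s0[k2]), log = TRUE)
        m <- max(lp)
        li <- m + log(sum(exp(lp - m)) * (g1[2] - g1[1]) * (g2[2] - g2[1]))
      }
      comp_int[k1, k2] <- log(w0[k1]) + log(w0[k2]) + li
    }
  }
  m <- max(comp_int)
  m + log(sum(exp(comp_int - m)))
}

ridge_solution <- function(X, Y, lambda) {
  solve(crossprod(X) + lambda * diag(ncol(X)), crossprod(X, Y))
}

# Orthonormal-column design matrix.
orthonormal_X <- function(n, p) {
  qr.Q(qr(matrix(rnorm(n * p), n, p)))[, seq_len(p), drop = FALSE]
}

mean_std_rmse <- function(Y_true, Y_pred) {
  mean(vapply(seq_len(ncol(Y_true)), function(s)
    standardized_rmse(Y_true[, s], Y_pred[, s]), numeric(1)))
}
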