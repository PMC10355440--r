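test_that("single-predictor sufficient statistics match per-column least squares", {
  # hand-checked orthonormal case
  st <- univariate_stats(c(1, -1), rbind(c(2, 0), c(-2, 0)), diag(2))
  expect_equal(st$bhat, c(2, 0))
  expect_equal(st$S, diag(2) / 2)

  # zero residuals give a zero estimate
  st0 <- univariate_stats(rnorm(10), matrix(0, 10, 3), diag(3))
  expect_equal(st0$bhat, rep(0, 3))

  # random case against r separate one-predictor least-squares fits
  set.seed(11)
  x <- rnorm(50)
  R <- matrix(rnorm(150), 50, 3)
  V <- crossprod(matrix(rnorm(9), 3, 3)) + diag(3)
  st <- univariate_stats(x, R, V)
  ols <- vapply(1:3, function(s) unname(coef(lm(R[, s] ~ x + 0))), numeric(1))
  expect_equal(st$bhat, ols, tolerance = 1e-10)
  expect_equal(st$S, V / sum(x^2), tolerance = 1e-12)

  expect_error(univariate_stats(rep(0, 5), matrix(0, 5, 2), diag(2)),
               "constant predictor")
})

test_that("mixture posterior matches conjugate-normal arithmetic in one dimension", {
  # point-mass (null-only) prior pins the posterior at zero
  pr0 <- mixture_prior(list(matrix(0, 2, 2)), 1, "null")
  post <- bmsr_mix_posterior(c(1.3, -0.4), diag(2) * 0.1, pr0)
  expect_equal(post$w1, 1)
  expect_equal(post$mean, c(0, 0))
  expect_equal(post$second_moment, matrix(0, 2, 2))

  # univariate conjugate: S0 = 0.16, S = 0.04, bhat = 0.5
  pr <- mixture_prior(list(matrix(0.16, 1, 1)), 1, "slab")
  post <- bmsr_mix_posterior(0.5, matrix(0.04, 1, 1), pr)
  expect_equal(post$mean, 0.4, tolerance = 1e-12)
  expect_equal(post$second_moment[1, 1] - post$mean^2, 0.032,
               tolerance = 1e-12)
  # and against numerical integration
  qo <- quadrature_posterior(0.5, matrix(0.04, 1, 1),
                             list(matrix(0.16, 1, 1)), 1)
  expect_equal(post$mean, qo$mean, tolerance = 1e-8)
  expect_equal(post$second_moment, qo$second_moment, tolerance = 1e-8)
})

test_that("posterior is symmetric at the origin", {
  pr <- mixture_prior(list(matrix(0, 2, 2), diag(2), matrix(1, 2, 2)),
                      c(0.3, 0.4, 0.3), c("null", "indep", "equal"))
  S <- diag(2) * 0.25
  post <- bmsr_mix_posterior(c(0, 0), S, pr)
  expect_equal(post$mean, c(0, 0))
  lw <- vapply(seq_len(pr$K), function(k)
    pr$w0[k] * exp(log_dmvnorm(c(0, 0), c(0, 0), pr$S0[[k]] + S)),
    numeric(1))
  expect_equal(post$w1, lw / sum(lw), tolerance = 1e-12)
})

test_that("responsibilities stay normalized for extreme effect estimates", {
  set.seed(21)
  pr <- expand_with_scale_grid(canonical_covariances(3),
                               c(0.01, 0.1, 1))
  S <- crossprod(matrix(rnorm(9), 3, 3)) / 3 + 0.1 * diag(3)
  for (scale in c(0.1, 1, 10, 1e3)) {
    bhat <- scale * sqrt(sum(diag(S))) * rnorm(3)
    post <- bmsr_mix_posterior(bhat, S, pr)
    expect_equal(sum(post$w1), 1, tolerance = 1e-10)
    expect_true(all(post$w1 >= 0))
    expect_true(all(is.finite(post$mean)))
  }
})

test_that("the posterior mean shrinks the estimate in the S-inverse norm", {
  set.seed(22)
  for (i in 1:20) {
    S <- crossprod(matrix(rnorm(4), 2, 2)) / 2 + 0.05 * diag(2)
    S0 <- crossprod(matrix(rnorm(4), 2, 2))
    pr <- mixture_prior(list(S0), 1, "slab")
    bhat <- rnorm(2, sd = 2)
    post <- bmsr_mix_posterior(bhat, S, pr)
    Sinv <- solve(S)
    expect_lte(sqrt(drop(post$mean %*% Sinv %*% post$mean)),
               sqrt(drop(bhat %*% Sinv %*% bhat)) + 1e-12)
  }
})

test_that("permuting conditions permutes the posterior identically", {
  set.seed(23)
  r <- 4
  perm <- c(3, 1, 4, 2)
  S <- crossprod(matrix(rnorm(r * r), r, r)) / r + 0.1 * diag(r)
  S0s <- list(matrix(0, r, r), crossprod(matrix(rnorm(r * r), r, r)),
              diag(c(1, 0, 2, 0.5)))
  pr <- mixture_prior(S0s, c(0.2, 0.5, 0.3))
  bhat <- rnorm(r)
  post <- bmsr_mix_posterior(bhat, S, pr)
  pr_p <- mixture_prior(lapply(S0s, function(m) m[perm, perm]),
                        c(0.2, 0.5, 0.3))
  post_p <- bmsr_mix_posterior(bhat[perm], S[perm, perm], pr_p)
  expect_equal(post_p$w1, post$w1, tolerance = 1e-12)
  expect_equal(post_p$mean, post$mean[perm], tolerance = 1e-12)
  expect_equal(post_p$second_moment, post$second_moment[perm, perm],
               tolerance = 1e-12)
})

test_that("posterior moment invariants hold on random instances", {
  set.seed(24)
  pr <- expand_with_scale_grid(canonical_covariances(3), c(0.05, 0.5))
  for (i in 1:10) {
    S <- crossprod(matrix(rnorm(9), 3, 3)) / 3 + 0.05 * diag(3)
    post <- bmsr_mix_posterior(rnorm(3), S, pr)
    expect_equal(sum(post$w1), 1, tolerance = 1e-10)
    expect_equal(post$mean, as.vector(post$mu1 %*% post$w1),
                 tolerance = 1e-12)
    covb <- post$second_moment - tcrossprod(post$mean)
    expect_gte(min(eigen(covb, symmetric = TRUE,
                         only.values = TRUE)$values), -1e-8)
  }
})
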