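test_that("with one predictor the fit reduces to the single-variable posterior", {
  set.seed(41)
  n <- 40
  r <- 3
  x <- rnorm(n)
  V <- diag(r) * 0.5
  Y <- x %*% t(c(1, 0.5, 0)) + matrix(rnorm(n * r), n, r) %*% chol(V)
  pr <- expand_with_scale_grid(canonical_covariances(r), c(0.1, 0.5))
  fit <- mr_mash(matrix(x, n, 1), Y, prior = pr, V_init = V,
                 update_w0 = FALSE, update_V = FALSE, intercept = FALSE,
                 standardize = FALSE, max_iter = 1)
  st <- univariate_stats(x, Y, V)
  ref <- bmsr_mix_posterior(st$bhat, st$S, pr)
  expect_equal(as.vector(fit$Bbar), ref$mean, tolerance = 1e-12)
  expect_equal(as.vector(fit$W1), ref$w1, tolerance = 1e-12)
  expect_equal(as.vector(fit$Bhat), st$bhat, tolerance = 1e-12)
  # accessor reconstructs the same posterior
  post <- mr_mash_posterior(fit, 1)
  expect_equal(post$mean, ref$mean, tolerance = 1e-12)
  expect_equal(post$second_moment, ref$second_moment, tolerance = 1e-12)
})

test_that("an isotropic one-component prior recovers the ridge estimator", {
  set.seed(42)
  n <- 40
  p <- 6
  r <- 3
  X <- orthonormal_X(n, p)
  Y <- matrix(rnorm(n * r), n, r)
  s2 <- 0.3
  tau2 <- 0.7
  pr <- mixture_prior(list(s2 * diag(r)), 1, "iso")
  fit <- mr_mash(X, Y, prior = pr, V_init = tau2 * diag(r),
                 update_w0 = FALSE, update_V = FALSE, intercept = FALSE,
                 standardize = FALSE, tol = 1e-10, coef_tol = 1e-10,
                 max_iter = 200)
  ridge <- ridge_solution(X, Y, tau2 / s2)
  expect_equal(unname(fit$Bbar), ridge, tolerance = 1e-8)
})

test_that("the ELBO trace is nondecreasing across update configurations", {
  set.seed(43)
  cfgs <- list(list(update_w0 = TRUE, update_V = TRUE, miss = 0),
               list(update_w0 = TRUE, update_V = FALSE, miss = 0),
               list(update_w0 = FALSE, update_V = TRUE, miss = 0.3),
               list(update_w0 = TRUE, update_V = TRUE, miss = 0.3))
  for (cfg in cfgs) {
    for (seed in 1:3) {
      sim <- simulate_scenario(scenario_spec("B", n = 120, p = 15, r = 4,
                                             n_causal = 3,
                                             missing_rate = cfg$miss,
                                             seed = seed))
      pr <- expand_with_scale_grid(canonical_covariances(4), c(0.05, 0.3))
      fit <- mr_mash(sim$train, prior = pr, update_w0 = cfg$update_w0,
                     update_V = cfg$update_V, max_iter = 100)
      expect_gte(min(diff(fit$elbo_trace)), -1e-6)
    }
  }
})

test_that("with a null prior and zero effects the ELBO equals the exact log-likelihood", {
  set.seed(44)
  n <- 25
  r <- 2
  V <- matrix(c(1, 0.3, 0.3, 0.8), 2, 2)
  Y <- matrix(rnorm(n * r), n, r) %*% chol(V)
  X <- matrix(rnorm(n * 3), n, 3)
  pr <- mixture_prior(list(matrix(0, r, r)), 1, "null")
  fit <- mr_mash(X, Y, prior = pr, V_init = V, update_w0 = FALSE,
                 update_V = FALSE, intercept = FALSE, standardize = FALSE,
                 max_iter = 2)
  R <- Y  # B is identically zero under the null prior
  loglik <- sum(log_dmvnorm_rows(R, c(0, 0), V))
  expect_equal(fit$elbo_trace[length(fit$elbo_trace)], loglik,
               tolerance = 1e-10)
})

test_that("predictions follow the linear model and training predictions are consistent", {
  # hand arithmetic: b0 = (1, -1), B = ((1, 0), (0, 2)), x = (3, 4)
  set.seed(45)
  n <- 30
  X <- matrix(rnorm(n * 2), n, 2)
  B <- rbind(c(1, 0), c(0, 2))
  Y <- rep(c(1, -1), each = n) + X %*% B + 0.01 * matrix(rnorm(n * 2), n, 2)
  pr <- expand_with_scale_grid(list(diag(2)), c(1, 4), labels = "indep")
  fit <- mr_mash(X, Y, prior = pr, standardize = FALSE)
  yh <- predict(fit, rbind(c(3, 4)))
  expect_equal(dim(yh), c(1L, 2L))
  expect_equal(as.vector(yh), c(4, 7), tolerance = 0.05)

  # training-set predictions equal the fitted means of the final iteration
  expect_equal(unname(predict(fit, X)), unname(fitted(fit)),
               tolerance = 1e-12)

  # a zero-coefficient fit predicts the intercept everywhere
  fit0 <- mr_mash(X, Y, prior = mixture_prior(list(matrix(0, 2, 2)), 1,
                                              "null"),
                  update_w0 = FALSE, max_iter = 2)
  yh0 <- predict(fit0, matrix(rnorm(10), 5, 2))
  expect_equal(unname(yh0), matrix(rep(fit0$b0, each = 5), 5, 2),
               tolerance = 1e-12)

  expect_error(predict(fit, matrix(0, 2, 5)), "columns")
})

test_that("standardization is undone for coefficients and predictions", {
  set.seed(46)
  sim <- simulate_scenario(scenario_spec("A", n = 200, p = 20, r = 3,
                                         n_causal = 3, seed = 7))
  pr <- expand_with_scale_grid(canonical_covariances(3), c(0.05, 0.3))
  fit_std <- mr_mash(sim$train, prior = pr, standardize = TRUE)
  co <- coef(fit_std)
  expect_equal(dim(co), c(21L, 3L))
  manual <- rep(co[1, ], each = nrow(sim$test$X)) +
    sim$test$X %*% co[-1, ]
  expect_equal(unname(predict(fit_std, sim$test$X)), unname(manual),
               tolerance = 1e-10)
})

test_that("fits are deterministic given identical inputs and options", {
  sim <- simulate_scenario(scenario_spec("B", n = 150, p = 20, r = 3,
                                         n_causal = 3, missing_rate = 0.2,
                                         seed = 48))
  pr <- expand_with_scale_grid(canonical_covariances(3), c(0.05, 0.3))
  f1 <- mr_mash(sim$train, prior = pr)
  f2 <- mr_mash(sim$train, prior = pr)
  expect_identical(f1$Bbar, f2$Bbar)
  expect_identical(f1$elbo_trace, f2$elbo_trace)
  expect_identical(f1$V, f2$V)
})

test_that("iteration budget is honored and reported", {
  sim <- simulate_scenario(scenario_spec("A", n = 100, p = 10, r = 3,
                                         n_causal = 2, seed = 49))
  pr <- expand_with_scale_grid(canonical_covariances(3), c(0.1))
  fit <- mr_mash(sim$train, prior = pr, max_iter = 1)
  expect_false(fit$converged)
  expect_length(fit$elbo_trace, 1)
})

test_that("constant predictors are rejected with a clear error", {
  X <- cbind(1, matrix(rnorm(40), 20, 2))
  Y <- matrix(rnorm(40), 20, 2)
  pr <- expand_with_scale_grid(list(diag(2)), 0.5, labels = "i")
  expect_error(mr_mash(X, Y, prior = pr), "constant predictor")
})

test_that("per-iteration cost grows about linearly in the number of predictors", {
  set.seed(50)
  time_fit <- function(p) {
    sim <- simulate_scenario(scenario_spec("A", n = 300, p = p, r = 5,
                                           n_causal = 5, seed = 51))
    pr <- expand_with_scale_grid(canonical_covariances(5),
                                 c(0.05, 0.2, 0.8))
    min(vapply(1:3, function(i)
      system.time(mr_mash(sim$train, prior = pr, max_iter = 10,
                          tol = 1e-12, coef_tol = 0))[["elapsed"]],
      numeric(1)))
  }
  t1 <- time_fit(250)
  t2 <- time_fit(500)
  expect_lt(t2 / t1, 2.8)
})
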