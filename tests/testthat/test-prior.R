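test_that("canonical covariance collection enumerates the sharing patterns", {
  cc <- canonical_covariances(2)
  expect_length(cc$matrices, 7)  # I, ones, 2 singletons, 3 constant-corr
  expect_setequal(cc$labels,
                  c("independent", "equal", "singleton_1", "singleton_2",
                    "shared_0.25", "shared_0.5", "shared_0.75"))
  for (m in cc$matrices) {
    expect_equal(m, t(m))
    expect_gte(min(eigen(m, symmetric = TRUE, only.values = TRUE)$values),
               -1e-12)
  }
  # degenerate dimension collapses to a single unit matrix
  cc1 <- canonical_covariances(1)
  expect_length(cc1$matrices, 1)
  expect_equal(cc1$matrices[[1]], matrix(1, 1, 1))
})

test_that("scale-grid expansion counts, deduplicates and keeps the simplex", {
  one <- expand_with_scale_grid(list(diag(2)), scale_grid = 1,
                                labels = "indep")
  expect_equal(one$K, 2)  # null + one base
  expect_equal(one$labels[1], "null")

  pr <- expand_with_scale_grid(canonical_covariances(2),
                               scale_grid = c(0.05, 0.1, 0.2, 0.4, 0.8))
  expect_equal(pr$K, 36)  # 7 bases x 5 scales + null, no duplicates
  expect_equal(sum(pr$w0), 1, tolerance = 1e-15)

  # duplicates across scaled bases are removed
  dup <- expand_with_scale_grid(list(diag(2), 2 * diag(2)),
                                scale_grid = c(1, 2),
                                labels = c("a", "b"))
  expect_equal(dup$K, 4)  # null, I, 2I, 4I
  flat <- vapply(dup$S0, function(m) paste(signif(m, 12), collapse = ","),
                 character(1))
  expect_false(anyDuplicated(flat) > 0)
})

test_that("mixture prior validation enforces the simplex and PSD contracts", {
  expect_no_error(mixture_prior(list(diag(2)), w0 = 1))
  expect_error(mixture_prior(list(diag(2)), w0 = 0.9), "sum to 1")
  expect_error(mixture_prior(list(diag(2), diag(2)), w0 = c(1.2, -0.2)),
               "non-negative")
  asym <- matrix(c(1, 0.5, 0.2, 1), 2, 2)
  expect_error(mixture_prior(list(asym), 1), "symmetric")
  npd <- matrix(c(1, 2, 2, 1), 2, 2)
  expect_error(mixture_prior(list(npd), 1), "semi-definite")
  # a null component is moved first
  pr <- mixture_prior(list(diag(2), matrix(0, 2, 2)), c(0.7, 0.3),
                      c("slab", "null"))
  expect_equal(pr$labels[1], "null")
  expect_equal(pr$w0, c(0.3, 0.7))
})

test_that("data-driven covariances recover simulated sharing structure", {
  # strong equal effects across 5 conditions: leading pattern near-constant
  sim <- simulate_scenario(scenario_spec("A", n = 800, p = 100, r = 5,
                                         n_causal = 3, pve_high = 0.4,
                                         seed = 31))
  dd <- data_driven_covariances(sim$train$X, sim$train$Y, n_strong = 10)
  S <- dd$matrices[[1]]
  C <- cov2cor(S)
  expect_gte(min(C[upper.tri(C)]), 0.8)

  # strong condition-1-specific effects: trace concentrates on entry (1,1)
  simC <- simulate_scenario(scenario_spec("C", n = 1000, p = 100, r = 5,
                                          n_causal = 2, pve_high = 0.5,
                                          seed = 32))
  ddC <- data_driven_covariances(simC$train$X, simC$train$Y, n_strong = 5)
  SC <- ddC$matrices[[1]]
  expect_gte(SC[1, 1] / sum(diag(SC)), 0.9)

  # pure noise: completes and returns PSD matrices
  set.seed(33)
  Xn <- simulate_genotypes(200, 50)
  Yn <- matrix(rnorm(200 * 4), 200, 4)
  ddn <- data_driven_covariances(Xn, Yn, n_strong = 20)
  for (m in ddn$matrices)
    expect_gte(min(eigen(m, symmetric = TRUE, only.values = TRUE)$values),
               -1e-10)
})

test_that("data-driven estimation commutes with condition relabeling", {
  sim <- simulate_scenario(scenario_spec("D", n = 400, p = 80, r = 5,
                                         n_causal = 8, seed = 34))
  perm <- c(4, 2, 5, 1, 3)
  dd <- data_driven_covariances(sim$train$X, sim$train$Y, n_strong = 15)
  ddp <- data_driven_covariances(sim$train$X, sim$train$Y[, perm],
                                 n_strong = 15)
  expect_equal(ddp$matrices[[1]], dd$matrices[[1]][perm, perm],
               tolerance = 1e-10)
})
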