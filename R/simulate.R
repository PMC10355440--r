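#' Specification of a multi-condition simulation scenario
#'
#' Describes a simulated genotype-to-multi-condition-outcome dataset with a
#' controlled pattern of effect sharing.  Scenarios:
#' \describe{
#'   \item{A "Equal Effects"}{each causal variant has the same effect in
#'     every condition.}
#'   \item{B "Independent Effects"}{each causal variant affects every
#'     condition with independent effects.}
#'   \item{C "Mostly Null"}{causal variants affect condition 1 only.}
#'   \item{D "Equal Effects + Null"}{equal effects within `subgroup1`
#'     (default conditions 1-3), none elsewhere.}
#'   \item{E "Shared Effects in Subgroups"}{each causal variant is assigned
#'     by a fair coin to `subgroup1` or its complement; within the assigned
#'     subgroup effects are drawn multivariate normal with constant
#'     correlation 0.8 (shared, but unequal), zero elsewhere.  Subgroup-1
#'     effects explain `pve_high` of each affected condition's variance,
#'     subgroup-2 effects `pve_low`.}
#' }
#' Causal effects are scaled so they explain `pve_high` (scenarios A-D) of
#' the variance of each affected condition; total variance per condition is
#' normalized to 1 so standardized RMSE is directly interpretable.
#'
#' @param scenario One of `"A"`, `"B"`, `"C"`, `"D"`, `"E"`.
#' @param n Total number of samples (split into training and test).
#' @param p Number of predictors (genotype-like dosages).
#' @param r Number of conditions (default 10).
#' @param n_causal Number of causal predictors (default 5).
#' @param pve_high Proportion of variance explained in affected conditions
#'   (default 0.20).
#' @param pve_low Low-signal PVE for the second subgroup in scenario E
#'   (default 0.05).
#' @param subgroup1 Condition indices of the first subgroup (default 1:3).
#' @param missing_rate Fraction of training outcome entries set to missing
#'   (default 0).
#' @param test_fraction Fraction of samples held out for testing
#'   (default 0.2).
#' @param maf_range Range of minor-allele frequencies (default
#'   `c(0.05, 0.5)`).
#' @param resid_cor Exchangeable residual correlation across conditions
#'   (default 0, i.e. diagonal residual covariance).
#' @param seed Integer seed; the dataset is a deterministic function of the
#'   spec including the seed.
#' @return An object of class `"scenario_spec"`.
#' @export
scenario_spec <- function(scenario = c("A", "B", "C", "D", "E"),
                          n = 600, p = 200, r = 10, n_causal = 5,
                          pve_high = 0.20, pve_low = 0.05,
                          subgroup1 = 1:3, missing_rate = 0,
                          test_fraction = 0.2, maf_range = c(0.05, 0.5),
                          resid_cor = 0, seed = 1) {
  scenario <- match.arg(scenario)
  if (n_causal > p) stop("n_causal must not exceed p")
  if (pve_high < 0 || pve_high >= 1 || pve_low < 0 || pve_low >= 1)
    stop("pve values must be in [0, 1)")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must be in [0, 1)")
  if (!all(subgroup1 %in% seq_len(r)))
    stop("subgroup1 must be a subset of 1..r")
  if (scenario %in% c("C", "D", "E")) {
    if (scenario == "C" && r < 2)
      stop("scenario C requires r >= 2")
    if (scenario %in% c("D", "E") && length(subgroup1) >= r)
      stop("scenario ", scenario, " requires subgroup1 to be a strict ",
           "subset of the conditions")
  }
  structure(list(scenario = scenario, n = n, p = p, r = r,
                 n_causal = n_causal, pve_high = pve_high, pve_low = pve_low,
                 subgroup1 = as.integer(subgroup1),
                 missing_rate = missing_rate, test_fraction = test_fraction,
                 maf_range = maf_range, resid_cor = resid_cor,
                 seed = as.integer(seed)),
            class = "scenario_spec")
}

#' Simulate genotype-like dosage predictors
#'
#' Each column j draws a minor-allele frequency uniformly from `maf_range`
#' and fills entries i.i.d. Binomial(2, MAF_j), mimicking unlinked biallelic
#' variant dosages.
#'
#' @param n,p Dimensions.
#' @param maf_range Length-2 range of allele frequencies.
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used.
#' @return n x p matrix of dosages in {0, 1, 2}, with attribute `"maf"`.
#' @export
simulate_genotypes <- function(n, p, maf_range = c(0.05, 0.5), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  maf <- runif(p, maf_range[1L], maf_range[2L])
  X <- matrix(rbinom(n * p, 2L, rep(maf, each = n)), n, p)
  storage.mode(X) <- "double"
  attr(X, "maf") <- maf
  X
}

#' Draw unscaled causal effects for a scenario
#'
#' Base draws are standard normal before PVE scaling; see [scenario_spec()]
#' for the per-scenario sharing structure.
#'
#' @param spec A [scenario_spec].
#' @param causal_indices Indices of the causal predictors.
#' @return p x r matrix of raw effects, zero outside `causal_indices`, with
#'   attribute `"subgroup"` (scenario E only): 1 or 2 per causal variant.
#' @export
simulate_effects <- function(spec, causal_indices) {
  p <- spec$p
  r <- spec$r
  nc <- length(causal_indices)
  B <- matrix(0, p, r)
  sub1 <- spec$subgroup1
  sub2 <- setdiff(seq_len(r), sub1)
  assign <- NULL
  if (spec$scenario == "A") {
    B[causal_indices, ] <- rnorm(nc)
  } else if (spec$scenario == "B") {
    B[causal_indices, ] <- matrix(rnorm(nc * r), nc, r)
  } else if (spec$scenario == "C") {
    B[causal_indices, 1L] <- rnorm(nc)
  } else if (spec$scenario == "D") {
    B[causal_indices, sub1] <- rnorm(nc)
  } else {
    assign <- 1L + rbinom(nc, 1L, 0.5)
    # both subgroups must be represented, else their PVE targets are
    # unattainable; re-draw the fair coin until they are
    while (nc >= 2 && length(unique(assign)) < 2L)
      assign <- 1L + rbinom(nc, 1L, 0.5)
    for (i in seq_len(nc)) {
      grp <- if (assign[i] == 1L) sub1 else sub2
      m <- length(grp)
      C <- matrix(0.8, m, m)
      diag(C) <- 1
      B[causal_indices[i], grp] <- drop(rnorm(m) %*% chol(C))
    }
  }
  attr(B, "subgroup") <- assign
  B
}

# Per-condition PVE targets for a scenario.
.pve_targets <- function(spec) {
  r <- spec$r
  sub1 <- spec$subgroup1
  switch(spec$scenario,
         A = rep(spec$pve_high, r),
         B = rep(spec$pve_high, r),
         C = c(spec$pve_high, rep(0, r - 1L)),
         D = {
           v <- rep(0, r)
           v[sub1] <- spec$pve_high
           v
         },
         E = {
           v <- rep(spec$pve_low, r)
           v[sub1] <- spec$pve_high
           v
         })
}

#' Scale raw effects to hit per-condition PVE targets
#'
#' Rescales each column of the raw effect matrix so that, on the supplied
#' (training) predictor matrix, the genetic variance equals the scenario's
#' per-condition PVE target, and sets the residual variance so the total
#' variance of each condition is 1: `Var(X b_s) = pve_s`,
#' `V_ss = 1 - pve_s`.  Conditions with a zero PVE target keep an all-zero
#' effect column and unit residual variance.  In scenario E each condition
#' belongs to exactly one subgroup, so per-column scaling rescales each
#' subgroup's contribution to its own target.
#'
#' @param B_raw p x r raw effect matrix (from [simulate_effects()]).
#' @param X n x p predictor matrix used to measure genetic variance.
#' @param spec A [scenario_spec].
#' @return List with `B` (scaled effects), `V` (r x r residual covariance)
#'   and `pve` (the per-condition targets).
#' @export
scale_to_pve <- function(B_raw, X, spec) {
  pve <- .pve_targets(spec)
  r <- spec$r
  B <- B_raw
  vres <- rep(1, r)
  for (s in seq_len(r)) {
    if (pve[s] > 0) {
      g <- as.vector(X %*% B_raw[, s])
      v <- var(g)
      if (v <= 0)
        stop("condition ", s, " has PVE target ", pve[s],
             " but an all-zero effect column")
      B[, s] <- B_raw[, s] * sqrt(pve[s] / v)
      vres[s] <- 1 - pve[s]
    } else {
      if (any(B_raw[, s] != 0))
        stop("condition ", s, " has PVE target 0 but non-zero effects")
    }
  }
  V <- diag(sqrt(vres), r) %*%
    ((1 - spec$resid_cor) * diag(r) + spec$resid_cor) %*% diag(sqrt(vres), r)
  V <- 0.5 * (V + t(V))
  list(B = B, V = V, pve = pve)
}

#' Mask outcome entries completely at random
#'
#' Entries are masked i.i.d. Bernoulli(`missing_rate`); any row that would
#' lose all its entries is re-drawn, so every sample keeps at least one
#' observed outcome.
#'
#' @param Y n x r outcome matrix (only its dimensions are used).
#' @param missing_rate Missingness probability in [0, 1).
#' @param seed Optional integer seed.
#' @return n x r logical mask, `TRUE` = observed.
#' @export
apply_missingness <- function(Y, missing_rate, seed = NULL) {
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must be in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(Y)
  r <- ncol(Y)
  mask <- matrix(runif(n * r) >= missing_rate, n, r)
  bad <- which(rowSums(mask) == 0L)
  while (length(bad) > 0) {
    mask[bad, ] <- matrix(runif(length(bad) * r) >= missing_rate,
                          length(bad), r)
    bad <- bad[rowSums(mask[bad, , drop = FALSE]) == 0L]
  }
  mask
}

#' Simulate a complete multi-condition dataset under a scenario
#'
#' Generates genotype-like predictors, scenario-structured causal effects
#' scaled to the PVE targets, outcomes with unit total variance per
#' condition, a train/test split, and (optionally) missingness in the
#' training outcomes.  The whole dataset is a deterministic function of the
#' spec (including its seed).
#'
#' @param spec A [scenario_spec].
#' @return An object of class `"mr_sim"`: list with `train` (a
#'   [regression_data]), `test` (list with complete `X`, `Y`), `B_true`,
#'   `V_true`, `causal_indices`, `subgroup` (scenario E assignment, else
#'   `NULL`), `pve_target`, `pve_realized` (out-of-sample genetic variance
#'   fraction per condition), `maf`, and `spec`.
#' @examples
#' sim <- simulate_scenario(scenario_spec("A", n = 100, p = 20, r = 3,
#'                                        n_causal = 2, seed = 1))
#' sim$pve_realized
#' @export
simulate_scenario <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  set.seed(spec$seed)
  n <- spec$n
  p <- spec$p
  r <- spec$r
  X <- simulate_genotypes(n, p, spec$maf_range)
  maf <- attr(X, "maf")
  causal <- sort(sample.int(p, spec$n_causal))
  B_raw <- simulate_effects(spec, causal)
  subgroup <- attr(B_raw, "subgroup")

  n_test <- max(1L, round(spec$test_fraction * n))
  test_idx <- sort(sample.int(n, n_test))
  train_idx <- setdiff(seq_len(n), test_idx)

  sc <- scale_to_pve(B_raw, X[train_idx, , drop = FALSE], spec)
  B <- sc$B
  V <- sc$V
  E <- matrix(rnorm(n * r), n, r) %*% chol(V)
  Y <- X %*% B + E

  Y_train <- Y[train_idx, , drop = FALSE]
  mask <- if (spec$missing_rate > 0)
    apply_missingness(Y_train, spec$missing_rate)
  else matrix(TRUE, length(train_idx), r)

  X_test <- X[test_idx, , drop = FALSE]
  Y_test <- Y[test_idx, , drop = FALSE]
  g_test <- X_test %*% B
  pve_real <- vapply(seq_len(r), function(s)
    var(g_test[, s]) / var(Y_test[, s]), numeric(1))

  train <- regression_data(X[train_idx, , drop = FALSE], Y_train,
                           mask = mask)
  structure(list(train = train,
                 test = list(X = X_test, Y = Y_test),
                 B_true = B, V_true = V, causal_indices = causal,
                 subgroup = subgroup, pve_target = sc$pve,
                 pve_realized = pve_real, maf = maf, spec = spec),
            class = "mr_sim")
}

#' @export
print.mr_sim <- function(x, ...) {
  cat(sprintf(
    "mr_sim scenario %s: %d train + %d test samples, p = %d, r = %d, %d causal\n",
    x$spec$scenario, nrow(x$train$X), nrow(x$test$X), x$spec$p, x$spec$r,
    length(x$causal_indices)))
  cat("realized out-of-sample PVE:",
      paste(sprintf("%.3f", x$pve_realized), collapse = " "), "\n")
  invisible(x)
}

#' Draw fresh samples from a simulated dataset's generating model
#'
#' Generates new genotypes at the stored allele frequencies and outcomes
#' from the stored `B_true` and `V_true` — e.g. a large independent test set
#' for measuring population-level variance explained.
#'
#' @param sim An `"mr_sim"` object from [simulate_scenario()].
#' @param n_new Number of samples to draw.
#' @param seed Optional integer seed.
#' @return List with `X` (n_new x p) and `Y` (n_new x r).
#' @export
simulate_from_truth <- function(sim, n_new, seed = NULL) {
  stopifnot(inherits(sim, "mr_sim"))
  if (!is.null(seed)) set.seed(seed)
  p <- length(sim$maf)
  r <- ncol(sim$B_true)
  X <- matrix(rbinom(n_new * p, 2L, rep(sim$maf, each = n_new)), n_new, p)
  storage.mode(X) <- "double"
  Y <- X %*% sim$B_true +
    matrix(rnorm(n_new * r), n_new, r) %*% chol(sim$V_true)
  list(X = X, Y = Y)
}
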