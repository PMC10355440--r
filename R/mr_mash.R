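#' Fit a multivariate multiple regression with an adaptive mixture prior
#'
#' Fits `Y = 1 b0' + X B + E`, `E ~ MN(0, I_n, V)`, where each row of B has
#' the mixture-of-multivariate-normals prior `b_j ~ sum_k w0_k N_r(0, S0_k)`
#' held in `prior`.  Fitting is by coordinate-ascent variational inference
#' under a posterior that factorizes over the rows of B.  Each outer
#' iteration (i) imputes missing entries of Y from their conditional
#' distribution under the current model, (ii) sweeps over predictors
#' updating each row's mixture posterior in closed form, (iii) updates the
#' intercept, and (iv) evaluates the evidence lower bound (ELBO); between
#' iterations the mixture weights `w0` and residual covariance `V` are
#' re-estimated by empirical Bayes (maximizing the ELBO).  The recorded
#' ELBO trace is non-decreasing; a decrease beyond numerical slack raises an
#' error.
#'
#' The stored `V` and prior weights are those used in the final coordinate
#' sweep, so the returned posterior summaries are exactly self-consistent;
#' at convergence they agree with the post-sweep empirical Bayes updates to
#' within the convergence tolerance.
#'
#' @param X Numeric n x p predictor matrix (no missing values), or a
#'   [regression_data] object (in which case `Y` is ignored).
#' @param Y Numeric n x r outcome matrix; `NA` entries are treated as
#'   missing and imputed during fitting.
#' @param prior A [mixture_prior]; defaults to a data-driven prior built
#'   from the data via [mr_mash_prior()].
#' @param V_init Initial residual covariance; defaults to the empirical
#'   covariance of Y (pairwise complete), eigenvalue-clipped to be positive
#'   definite.
#' @param update_w0,update_V Estimate the mixture weights / residual
#'   covariance by empirical Bayes (defaults `TRUE`).
#' @param V_structure `"dense"` (default) or `"diagonal"` residual
#'   covariance updates.
#' @param standardize Scale predictor columns to unit standard deviation for
#'   fitting (default `TRUE`); predictions are always returned on the
#'   original scale.
#' @param intercept Include the intercept b0 (default `TRUE`); when `TRUE`,
#'   X is centered internally and b0 recovered each iteration.
#' @param tol Convergence tolerance on the ELBO change (default 1e-2).
#' @param coef_tol Secondary guard: also require the maximum absolute change
#'   in the posterior-mean coefficients to fall below this (default 1e-6).
#' @param max_iter Maximum outer iterations (default 5000).
#' @param w0_threshold Components whose updated weight falls below this are
#'   frozen at zero but retained for label stability (default 1e-8).
#' @param init Optional p x r matrix of initial coefficients on the scale of
#'   `X` as supplied (e.g. from a lasso-family fit); default zeros.
#' @param verbose Print per-iteration ELBO (default `FALSE`).
#'
#' @return An object of class `"mr_mash"`: a list with elements `b0`
#'   (length-r intercept), `Bbar` (p x r posterior-mean coefficients on the
#'   internal working scale of X; use [coef()] for the original scale), `V`
#'   (r x r residual covariance), `prior` (the [mixture_prior] with
#'   estimated weights), `W1` (p x K responsibilities), `Bhat` and `xtx`
#'   (final single-predictor statistics, see [mr_mash_posterior()]),
#'   `elbo_trace`, `n_iter`, `converged`, `Y_imputed` (Y with missing
#'   entries replaced by posterior means), centering/scaling constants, and
#'   the matched call.
#'
#' @seealso [predict.mr_mash()], [coef.mr_mash()], [mr_mash_posterior()],
#'   [report_top_pattern()]
#' @examples
#' sim <- simulate_scenario(scenario_spec("A", n = 150, p = 20, r = 3,
#'                                        n_causal = 2, seed = 1))
#' pr <- expand_with_scale_grid(canonical_covariances(3), c(0.1, 0.5))
#' fit <- mr_mash(sim$train$X, sim$train$Y, prior = pr)
#' fit
#' @export
mr_mash <- function(X, Y = NULL, prior = NULL, V_init = NULL,
                    update_w0 = TRUE, update_V = TRUE,
                    V_structure = c("dense", "diagonal"),
                    standardize = TRUE, intercept = TRUE,
                    tol = 1e-2, coef_tol = 1e-6, max_iter = 5000,
                    w0_threshold = 1e-8, init = NULL, verbose = FALSE) {
  cl <- match.call()
  V_structure <- match.arg(V_structure)
  if (inherits(X, "regression_data")) {
    data <- X
  } else {
    data <- regression_data(X, Y)
  }
  if (max_iter < 1) stop("max_iter must be at least 1")
  if (tol <= 0) stop("tol must be positive")
  if (w0_threshold < 0 || w0_threshold > 1e-2)
    stop("w0_threshold must be in [0, 1e-2]")
  X <- data$X
  Y <- data$Y
  mask <- data$mask
  n <- nrow(X)
  p <- ncol(X)
  r <- ncol(Y)
  const <- attr(data, "constant_predictors")
  if (length(const) > 0)
    stop("constant predictor column(s): ", paste(const, collapse = ", "),
         "; remove them before fitting")

  if (is.null(prior))
    prior <- mr_mash_prior(X, Y)
  if (!inherits(prior, "mixture_prior"))
    stop("prior must be a mixture_prior object")
  if (prior$r != r)
    stop("prior dimension (", prior$r, ") does not match ncol(Y) = ", r)
  K <- prior$K
  S0cube <- array(unlist(prior$S0), c(r, r, K))

  # working predictor matrix: centered iff intercept, scaled iff standardize
  cx <- if (intercept) colMeans(X) else rep(0, p)
  Xc <- sweep(X, 2L, cx)
  sx <- if (standardize) apply(Xc, 2L, sd) else rep(1, p)
  if (any(!is.finite(sx) | sx <= 0))
    stop("cannot standardize: zero-variance predictor column(s)")
  Xc <- sweep(Xc, 2L, sx, "/")
  xtx <- colSums(Xc^2)
  sig <- signif(xtx, 12)
  gxtx <- unique(sig)
  grp <- match(sig, gxtx)

  has_missing <- !all(mask)
  groups <- if (has_missing) .mask_groups(mask) else NULL

  # initial state
  obs_colmeans <- vapply(seq_len(r),
                         function(s) mean(Y[mask[, s], s]), numeric(1))
  b0 <- if (intercept) obs_colmeans else rep(0, r)
  Mu <- matrix(0, p, r)
  if (!is.null(init)) {
    init <- as.matrix(init)
    if (!identical(dim(init), c(p, r)))
      stop("init must be a ", p, " x ", r, " matrix")
    Mu <- init * sx  # convert to working (scaled-X) parametrization
  }
  if (is.null(V_init)) {
    V <- cov(Y, use = "pairwise.complete.obs")
    V[!is.finite(V)] <- 0
    V <- .make_pd(V)
  } else {
    V <- .make_pd(as.matrix(V_init), clip = FALSE)
  }
  w0 <- prior$w0

  Ytil <- Y
  if (has_missing)
    Ytil[!mask] <- rep(obs_colmeans, each = n)[!as.vector(mask)]
  Rbar <- Ytil - rep(b0, each = n) - Xc %*% Mu

  elbo_trace <- numeric(0)
  converged <- FALSE
  chV <- chol(V)
  Vinv <- chol2inv(chV)
  logdetV <- 2 * sum(log(diag(chV)))
  Sigma_sum <- matrix(0, r, r)
  entropy <- 0
  sw <- NULL

  for (it in seq_len(max_iter)) {
    if (has_missing) {
      Mfit <- rep(b0, each = n) + Xc %*% Mu
      imp <- .impute_step(Y, mask, groups, Mfit, V)
      Ytil <- imp$Y_filled
      Sigma_sum <- imp$Sigma_sum
      entropy <- imp$entropy
      Rbar <- Ytil - rep(b0, each = n) - Xc %*% Mu
    }
    sw <- .mr_mash_sweep(Xc, Rbar, Mu, xtx, grp, gxtx, S0cube, w0, V, Vinv,
                         logdetV)
    Mu <- sw$Mu
    Rbar <- sw$Rbar
    if (intercept) {
      db <- colMeans(Rbar)
      b0 <- b0 + db
      Rbar <- sweep(Rbar, 2L, db)
    }
    ERSS <- crossprod(Rbar) + sw$var_part + Sigma_sum
    elbo <- .compute_elbo(n, r, logdetV, Vinv, ERSS, sw$negKL, entropy)
    if (verbose)
      cat(sprintf("iter %4d  ELBO %.6f\n", it, elbo))
    if (length(elbo_trace) > 0) {
      delta <- elbo - elbo_trace[length(elbo_trace)]
      if (delta < -1e-6)
        stop("ELBO decreased by ", format(-delta), " at iteration ", it,
             " (after the coordinate sweep); this indicates a numerical ",
             "problem in the fit")
      elbo_trace <- c(elbo_trace, elbo)
      if (delta < tol && sw$max_delta < coef_tol) {
        converged <- TRUE
        break
      }
    } else {
      elbo_trace <- elbo
    }
    if (it == max_iter) break
    # empirical Bayes updates used by the next iteration
    if (update_w0) {
      w0 <- as.numeric(sw$w1sum) / p
      w0[w0 < w0_threshold] <- 0
      if (sum(w0) <= 0)
        stop("all prior weights pruned to zero; lower w0_threshold")
      w0 <- w0 / sum(w0)
    }
    if (update_V) {
      Vn <- ERSS / n
      if (V_structure == "diagonal")
        Vn <- diag(diag(Vn), r)
      Vn <- 0.5 * (Vn + t(Vn))
      chV <- tryCatch(chol(Vn), error = function(e)
        stop("updated residual covariance V is not positive definite at ",
             "iteration ", it, call. = FALSE))
      V <- Vn
      Vinv <- chol2inv(chV)
      logdetV <- 2 * sum(log(diag(chV)))
    }
  }

  prior$w0 <- w0
  Mfit <- rep(b0, each = n) + Xc %*% Mu
  Y_imputed <- Y
  if (has_missing) {
    imp <- .impute_step(Y, mask, groups, Mfit, V)
    Y_imputed <- imp$Y_filled
  }
  dimnames(Mu) <- list(data$predictor_ids, data$condition_ids)
  structure(list(
    b0 = stats::setNames(b0, data$condition_ids),
    Bbar = Mu,
    V = V,
    prior = prior,
    W1 = sw$W1,
    Bhat = sw$Bhat,
    xtx = xtx,
    elbo_trace = elbo_trace,
    n_iter = length(elbo_trace),
    converged = converged,
    Y_imputed = Y_imputed,
    fitted_values = Mfit,
    center = cx,
    scale = sx,
    intercept = intercept,
    standardize = standardize,
    dims = c(n = n, p = p, r = r, K = K),
    predictor_ids = data$predictor_ids,
    condition_ids = data$condition_ids,
    options = list(update_w0 = update_w0, update_V = update_V,
                   V_structure = V_structure, tol = tol,
                   coef_tol = coef_tol, max_iter = max_iter,
                   w0_threshold = w0_threshold),
    call = cl), class = "mr_mash")
}

# Evidence lower bound from the accumulated fit state.  Gaussian
# likelihood term (with expected residual sum of squares ERSS, which
# includes posterior coefficient variances and imputation covariances)
# minus the coefficient KL, plus the entropy of the imputation posterior.
.compute_elbo <- function(n, r, logdetV, Vinv, ERSS, negKL, entropy) {
  lik <- -0.5 * (n * r * log(2 * pi) + n * logdetV + sum(Vinv * ERSS))
  parts <- c(likelihood = lik, negKL = negKL, entropy = entropy)
  if (any(!is.finite(parts)))
    stop("non-finite ELBO: first non-finite term is '",
         names(parts)[which(!is.finite(parts))[1L]], "'")
  unname(lik + negKL + entropy)
}

# Clip eigenvalues so the matrix is usable as an initial covariance.
.make_pd <- function(V, clip = TRUE) {
  V <- 0.5 * (V + t(V))
  e <- eigen(V, symmetric = TRUE)
  if (min(e$values) <= 0) {
    if (!clip)
      stop("V_init must be positive definite")
    floor_ev <- max(max(e$values) * 1e-6, 1e-8)
    e$values <- pmax(e$values, floor_ev)
    V <- e$vectors %*% (e$values * t(e$vectors))
    V <- 0.5 * (V + t(V))
  }
  V
}

# Group samples by missingness pattern so each pattern's conditional
# moments are computed once per iteration.
.mask_groups <- function(mask) {
  key <- apply(mask, 1L, function(z) paste(which(z), collapse = ","))
  incomplete <- which(!apply(mask, 1L, all))
  split(incomplete, key[incomplete])
}

# One imputation pass: fill missing entries of Y with their conditional
# mean given the observed entries under N(Mfit[i, ], V), and accumulate the
# conditional covariance (for the ERSS and V updates) and the entropy of
# the imputation posterior (for the ELBO).
.impute_step <- function(Y, mask, groups, Mfit, V) {
  n <- nrow(Y)
  r <- ncol(Y)
  Yf <- Y
  Yf[!mask] <- Mfit[!mask]
  Sigma_sum <- matrix(0, r, r)
  entropy <- 0
  for (g in groups) {
    o <- which(mask[g[1L], ])
    m <- which(!mask[g[1L], ])
    ng <- length(g)
    if (length(o) == 0L) {
      Sig <- V
    } else {
      Voo <- V[o, o, drop = FALSE]
      Gt <- tryCatch(solve(Voo, V[o, m, drop = FALSE]),
                     error = function(e)
                       stop("singular observed-block covariance V_oo for ",
                            "sample ", g[1L], call. = FALSE))
      Sig <- V[m, m, drop = FALSE] -
        V[m, o, drop = FALSE] %*% Gt
      Sig <- 0.5 * (Sig + t(Sig))
      resid_o <- Y[g, o, drop = FALSE] - Mfit[g, o, drop = FALSE]
      Yf[g, m] <- Mfit[g, m, drop = FALSE] + resid_o %*% Gt
    }
    ld <- 2 * sum(log(diag(chol(Sig))))
    Sfull <- matrix(0, r, r)
    Sfull[m, m] <- Sig
    Sigma_sum <- Sigma_sum + ng * Sfull
    entropy <- entropy + ng * 0.5 * (length(m) * (log(2 * pi) + 1) + ld)
  }
  list(Y_filled = Yf, Sigma_sum = Sigma_sum, entropy = entropy)
}

#' Impute missing outcome entries under a fitted (or given) model
#'
#' Fills each missing entry of Y with its conditional mean given the
#' sample's observed entries under the model `y_i ~ N(b0 + B' x_i, V)`:
#' `mu_m + V_mo V_oo^{-1} (y_o - mu_o)`, and returns the conditional
#' covariance `V_mm - V_mo V_oo^{-1} V_om` of the filled block for each
#' sample (zero on observed coordinates).  Samples with no observed entries
#' receive the prior-predictive mean and full covariance V.
#'
#' @param Y Numeric n x r outcome matrix.
#' @param mask Logical n x r matrix, `TRUE` where observed; defaults to
#'   `!is.na(Y)`.
#' @param b0 Length-r intercept.
#' @param Bbar p x r coefficient matrix (on the scale of `X`).
#' @param X Numeric n x p predictor matrix.
#' @param V Symmetric positive-definite r x r residual covariance.
#' @return List with `Y_filled` (observed entries passed through) and
#'   `cov_contrib` (r x r x n array of per-sample conditional covariances).
#' @export
impute_missing <- function(Y, mask = NULL, b0, Bbar, X, V) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  r <- ncol(Y)
  mask <- if (is.null(mask)) !is.na(Y) else as.matrix(mask) & !is.na(Y)
  Mfit <- rep(as.numeric(b0), each = n) + as.matrix(X) %*% as.matrix(Bbar)
  cov_contrib <- array(0, c(r, r, n))
  if (all(mask))
    return(list(Y_filled = Y, cov_contrib = cov_contrib))
  groups <- split(seq_len(n)[!apply(mask, 1L, all)],
                  apply(mask, 1L, function(z) paste(which(z), collapse = ","))[
                    !apply(mask, 1L, all)])
  out <- .impute_step(Y, mask, groups, Mfit, V)
  for (g in groups) {
    m <- which(!mask[g[1L], ])
    o <- which(mask[g[1L], ])
    if (length(o) == 0L) {
      Sig <- V
    } else {
      Gt <- solve(V[o, o, drop = FALSE], V[o, m, drop = FALSE])
      Sig <- V[m, m, drop = FALSE] - V[m, o, drop = FALSE] %*% Gt
      Sig <- 0.5 * (Sig + t(Sig))
    }
    for (i in g) cov_contrib[m, m, i] <- Sig
  }
  list(Y_filled = out$Y_filled, cov_contrib = cov_contrib)
}

#' Full mixture posterior of one predictor's effect vector
#'
#' Reconstructs the per-predictor posterior (responsibilities, component
#' means and covariances, blended mean and second moment) from the stored
#' final-sweep statistics of a fitted model.  Row `j` of `fit$Bbar` equals
#' the blended posterior mean returned here.
#'
#' @param fit A fitted [mr_mash] object.
#' @param j Predictor index (1..p).
#' @return A `"bmsr_posterior"` object, as from [bmsr_mix_posterior()].
#' @export
mr_mash_posterior <- function(fit, j) {
  stopifnot(inherits(fit, "mr_mash"))
  p <- fit$dims[["p"]]
  if (j < 1 || j > p) stop("j must be in 1..", p)
  bmsr_mix_posterior(fit$Bhat[j, ], fit$V / fit$xtx[j], fit$prior)
}
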