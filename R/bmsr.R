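#' Sufficient statistics for a single-predictor multivariate regression
#'
#' Given one predictor x and an n x r matrix of expected residuals R, forms
#' the least-squares effect estimate across conditions and its sampling
#' covariance under residual covariance V: `bhat = R'x / (x'x)`,
#' `S = V / (x'x)`.  These are the inputs consumed by
#' [bmsr_mix_posterior()].
#'
#' @param x Numeric length-n predictor vector with positive sum of squares.
#' @param R Numeric n x r expected-residual matrix.
#' @param V Symmetric positive-definite r x r residual covariance.
#' @return List with `bhat` (length r) and `S` (r x r).
#' @examples
#' univariate_stats(c(1, -1), rbind(c(2, 0), c(-2, 0)), diag(2))
#' @export
univariate_stats <- function(x, R, V) {
  x <- as.numeric(x)
  R <- as.matrix(R)
  V <- as.matrix(V)
  if (length(x) != nrow(R))
    stop("length(x) must equal nrow(R)")
  xtx <- sum(x^2)
  if (xtx <= 0)
    stop("constant predictor: x has zero sum of squares")
  list(bhat = as.vector(crossprod(R, x)) / xtx, S = V / xtx)
}

#' Posterior for Bayesian multivariate simple regression with a mixture prior
#'
#' Closed-form posterior of a single effect vector b with prior
#' `b ~ sum_k w0_k N_r(0, S0_k)` and likelihood `bhat | b ~ N_r(b, S)`.  The
#' posterior is again a mixture of multivariate normals with
#' responsibilities `w1_k` proportional to `w0_k N(bhat; 0, S0_k + S)`,
#' component means `mu1_k = S0_k (S0_k + S)^{-1} bhat` and covariances
#' `S1_k = S0_k (S0_k + S)^{-1} S`.  The multiplication form keeps singular
#' prior components (including the null, all-zero matrix) exact without ever
#' inverting S0_k; responsibilities are computed in log space with
#' max-subtraction so components whose likelihoods differ by hundreds of
#' log-units remain stable.
#'
#' @param bhat Length-r effect estimate.
#' @param S Symmetric positive-definite r x r sampling covariance.
#' @param prior A [mixture_prior].
#' @return An object of class `"bmsr_posterior"`: list with elements `w1`
#'   (responsibilities), `mu1` (r x K component means), `S1` (r x r x K
#'   component covariances), `mean` (blended posterior mean),
#'   `second_moment` (blended E[b b']), and `logZ` (log normalizer,
#'   log sum_k w0_k N(bhat; 0, S0_k + S)).
#' @examples
#' pr <- mixture_prior(list(matrix(0, 1, 1), matrix(0.16, 1, 1)),
#'                     c(0.5, 0.5), c("null", "slab"))
#' bmsr_mix_posterior(0.5, matrix(0.04, 1, 1), pr)$mean
#' @export
bmsr_mix_posterior <- function(bhat, S, prior) {
  bhat <- as.numeric(bhat)
  S <- as.matrix(S)
  if (!inherits(prior, "mixture_prior"))
    stop("prior must be a mixture_prior object")
  r <- prior$r
  K <- prior$K
  if (length(bhat) != r || nrow(S) != r)
    stop("bhat and S must match the prior dimension r = ", r)
  mu1 <- matrix(0, r, K)
  S1 <- array(0, c(r, r, K))
  lw <- numeric(K)
  for (k in seq_len(K)) {
    C <- prior$S0[[k]] + S
    C <- 0.5 * (C + t(C))
    L <- tryCatch(chol(C), error = function(e)
      stop("prior component ", k, ": S0 + S is not positive definite",
           call. = FALSE))
    ldC <- 2 * sum(log(diag(L)))
    Ci <- chol2inv(L)
    A <- prior$S0[[k]] %*% Ci
    mu1[, k] <- A %*% bhat
    S1k <- A %*% S
    S1[, , k] <- 0.5 * (S1k + t(S1k))
    quad <- sum(backsolve(L, bhat, transpose = TRUE)^2)
    lw[k] <- ifelse(prior$w0[k] > 0, log(prior$w0[k]), -Inf) -
      0.5 * (r * log(2 * pi) + ldC + quad)
  }
  m <- max(lw)
  if (!is.finite(m))
    stop("all mixture-component log-weights are non-finite for bhat = (",
         paste(format(bhat), collapse = ", "), ")")
  w1 <- exp(lw - m)
  z <- sum(w1)
  w1 <- w1 / z
  mean_b <- as.vector(mu1 %*% w1)
  second <- matrix(0, r, r)
  for (k in seq_len(K))
    second <- second + w1[k] * (S1[, , k] + tcrossprod(mu1[, k]))
  second <- 0.5 * (second + t(second))
  structure(list(w1 = w1, mu1 = mu1, S1 = S1, mean = mean_b,
                 second_moment = second, logZ = m + log(z)),
            class = "bmsr_posterior")
}
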