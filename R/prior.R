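#' Mixture-of-multivariate-normals prior on effect vectors
#'
#' Constructs and validates the prior b_j ~ sum_k w0_k N_r(0, S0_k).  The
#' covariance collection S0 encodes candidate effect-sharing patterns across
#' conditions; the weights w0 form a simplex.  If a null (all-zero)
#' component is present it is moved to the first position, the convention
#' the fitting and reporting code rely on.
#'
#' @param S0 List of K symmetric positive semi-definite r x r matrices.
#' @param w0 Numeric vector of K non-negative weights summing to one;
#'   defaults to uniform.
#' @param labels Character vector of K component labels; defaults to
#'   `"comp_k"`.
#'
#' @return An object of class `"mixture_prior"`: list with elements `S0`
#'   (list of matrices), `w0`, `labels`, `r`, `K`.
#'
#' @examples
#' p <- mixture_prior(list(matrix(0, 2, 2), diag(2)), c(0.5, 0.5),
#'                    c("null", "independent"))
#' p$K
#' @export
mixture_prior <- function(S0, w0 = NULL, labels = NULL) {
  if (!is.list(S0) || length(S0) == 0)
    stop("S0 must be a non-empty list of covariance matrices")
  K <- length(S0)
  S0 <- lapply(S0, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    m
  })
  r <- nrow(S0[[1L]])
  w0 <- w0 %||% rep(1 / K, K)
  labels <- labels %||% paste0("comp_", seq_len(K))
  if (length(w0) != K || length(labels) != K)
    stop("w0 and labels must have one entry per covariance matrix")
  if (any(w0 < 0))
    stop("w0 must be non-negative")
  if (abs(sum(w0) - 1) > 1e-12)
    stop("w0 must sum to 1 (got ", format(sum(w0)), ")")
  for (k in seq_len(K)) {
    m <- S0[[k]]
    if (nrow(m) != r || ncol(m) != r)
      stop("component ", k, ": expected a ", r, " x ", r, " matrix")
    if (max(abs(m - t(m))) > 1e-12 * max(1, max(abs(m))))
      stop("component ", k, ": matrix is not symmetric")
    ev <- min(eigen(m, symmetric = TRUE, only.values = TRUE)$values)
    if (ev < -1e-10)
      stop("component ", k, ": matrix is not positive semi-definite ",
           "(smallest eigenvalue ", format(ev), ")")
  }
  is_null <- vapply(S0, function(m) all(m == 0), logical(1))
  if (any(is_null)) {
    ord <- order(!is_null)  # stable: nulls first
    if (sum(is_null) > 1)
      stop("at most one null (all-zero) component is allowed")
    S0 <- S0[ord]
    w0 <- w0[ord]
    labels <- labels[ord]
  }
  structure(list(S0 = S0, w0 = as.numeric(w0), labels = as.character(labels),
                 r = r, K = K),
            class = "mixture_prior")
}

#' @export
print.mixture_prior <- function(x, ...) {
  cat(sprintf("mixture_prior: K = %d components on r = %d conditions\n",
              x$K, x$r))
  top <- order(x$w0, decreasing = TRUE)[seq_len(min(5L, x$K))]
  for (k in top)
    cat(sprintf("  %-30s w0 = %.4g\n", x$labels[k], x$w0[k]))
  if (x$K > 5) cat("  ...\n")
  invisible(x)
}

#' Canonical effect-sharing covariance patterns
#'
#' The pre-specified ("canonical") covariance patterns used in the prior:
#' independent effects (identity), equal effects (all-ones), one
#' condition-specific singleton per condition, and shared-with-heterogeneity
#' patterns with unit diagonal and constant off-diagonal correlation 0.25,
#' 0.5 and 0.75.  Matrices that coincide (which happens for r = 1) are
#' deduplicated, keeping the first label.
#'
#' @param r Number of conditions (r >= 1).
#' @return List with elements `matrices` (list of r x r PSD matrices) and
#'   `labels` (character vector).
#' @examples
#' length(canonical_covariances(2)$matrices)  # 7
#' @export
canonical_covariances <- function(r) {
  if (r < 1) stop("r must be at least 1")
  mats <- list(diag(r), matrix(1, r, r))
  labs <- c("independent", "equal")
  for (s in seq_len(r)) {
    m <- matrix(0, r, r)
    m[s, s] <- 1
    mats <- c(mats, list(m))
    labs <- c(labs, paste0("singleton_", s))
  }
  for (rho in c(0.25, 0.5, 0.75)) {
    m <- matrix(rho, r, r)
    diag(m) <- 1
    mats <- c(mats, list(m))
    labs <- c(labs, paste0("shared_", rho))
  }
  dedupe_covariances(mats, labs)
}

#' Data-driven effect-sharing covariance patterns
#'
#' Estimates covariance patterns from the strongest signals in the data, in
#' the spirit of multivariate adaptive shrinkage: (a) per-predictor,
#' per-condition simple-regression effect estimates and z-scores are
#' computed on the observed outcome entries (with X standardized); (b) the
#' `n_strong` predictors with the largest max-absolute z-score across
#' conditions are selected; (c) the empirical (uncentered) covariance of
#' their effect-estimate rows is returned, together with rank-1 outer
#' products of the top `n_pcs` principal axes of those rows.  Each matrix is
#' normalized so its largest diagonal entry is 1 (the scale grid supplies
#' magnitudes).
#'
#' @param X Numeric n x p predictor matrix, or a [regression_data] object
#'   (in which case `Y` is taken from it).
#' @param Y Numeric n x r outcome matrix, possibly with `NA`s.
#' @param n_strong Number of strong predictors to use; default
#'   `min(p, max(2 r, 100))`.  If fewer usable predictors are available, all
#'   are used with a warning.
#' @param n_pcs Number of rank-1 principal-axis components; default
#'   `min(3, r)`.
#' @return List with elements `matrices` and `labels`, as for
#'   [canonical_covariances()].
#' @export
data_driven_covariances <- function(X, Y = NULL, n_strong = NULL,
                                    n_pcs = NULL) {
  if (inherits(X, "regression_data")) {
    Y <- X$Y
    X <- X$X
  }
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  n <- nrow(X)
  p <- ncol(X)
  r <- ncol(Y)
  n_strong <- n_strong %||% min(p, max(2L * r, 100L))
  n_pcs <- n_pcs %||% min(3L, r)
  if (n_strong < r)
    stop("n_strong must be at least r")
  if (n_pcs < 0 || n_pcs > r)
    stop("n_pcs must be between 0 and r")

  Xs <- scale(X)
  bad <- !is.finite(colSums(Xs))
  Xs[, bad] <- 0
  B <- matrix(0, p, r)
  Z <- matrix(0, p, r)
  for (s in seq_len(r)) {
    obs <- which(!is.na(Y[, s]))
    ys <- Y[obs, s] - mean(Y[obs, s])
    Xo <- Xs[obs, , drop = FALSE]
    Xo <- sweep(Xo, 2L, colMeans(Xo))
    sxx <- colSums(Xo^2)
    sxx[sxx == 0] <- NA
    b <- as.vector(crossprod(Xo, ys)) / sxx
    rss <- sum(ys^2) - b^2 * sxx
    df <- max(length(obs) - 2L, 1L)
    se <- sqrt(pmax(rss, 0) / df / sxx)
    B[, s] <- ifelse(is.finite(b), b, 0)
    z <- b / se
    Z[, s] <- ifelse(is.finite(z), z, 0)
  }
  zmax <- apply(abs(Z), 1L, max)
  usable <- which(zmax > 0)
  if (length(usable) < n_strong) {
    warning("only ", length(usable), " usable predictors for data-driven ",
            "covariance estimation; using all of them")
    strong <- usable
  } else {
    strong <- usable[order(zmax[usable], decreasing = TRUE)[seq_len(n_strong)]]
  }
  Bs <- B[strong, , drop = FALSE]
  mats <- list(crossprod(Bs) / nrow(Bs))
  labs <- "ED"
  if (n_pcs > 0) {
    sv <- svd(Bs, nu = 0, nv = min(n_pcs, min(dim(Bs))))
    for (k in seq_len(ncol(sv$v))) {
      v <- sv$v[, k]
      mats <- c(mats, list(tcrossprod(v)))
      labs <- c(labs, paste0("PC", k))
    }
  }
  mats <- lapply(mats, function(m) {
    d <- max(diag(m))
    if (d > 0) m <- m / d
    0.5 * (m + t(m))
  })
  dedupe_covariances(mats, labs)
}

#' Expand covariance bases over a scale grid into a mixture prior
#'
#' Forms the outer product of a set of base covariance patterns with a grid
#' of scaling factors, {sigma^2 S : sigma^2 in grid, S in bases}, prepends a
#' null (all-zero) component when requested, deduplicates matrices that
#' coincide entrywise, and returns a [mixture_prior] with uniform initial
#' weights.
#'
#' @param bases List of r x r PSD matrices, or the list returned by
#'   [canonical_covariances()] / [data_driven_covariances()].
#' @param scale_grid Strictly positive scale factors (variances); default
#'   `c(0.01, 0.025, 0.05, 0.1, 0.2, 0.4, 0.8, 1.6)`, chosen to span small
#'   to large effects relative to unit outcome variance.
#' @param include_null Prepend the all-zero component (default `TRUE`).
#' @param labels Optional labels for the bases (ignored when `bases` carries
#'   its own labels).
#' @return A [mixture_prior] with uniform weights.
#' @examples
#' pr <- expand_with_scale_grid(canonical_covariances(2), c(0.1, 1))
#' pr$K  # 1 null + 7 bases x 2 scales
#' @export
expand_with_scale_grid <- function(bases,
                                   scale_grid = default_scale_grid(),
                                   include_null = TRUE, labels = NULL) {
  if (is.list(bases) && !is.null(bases$matrices)) {
    labels <- bases$labels
    bases <- bases$matrices
  }
  if (length(bases) == 0) stop("bases must be non-empty")
  if (length(scale_grid) == 0 || any(scale_grid <= 0))
    stop("scale_grid must be non-empty and strictly positive")
  scale_grid <- sort(scale_grid)
  labels <- labels %||% paste0("base_", seq_along(bases))
  r <- nrow(bases[[1L]])
  mats <- list()
  labs <- character(0)
  for (i in seq_along(bases)) {
    for (s2 in scale_grid) {
      mats <- c(mats, list(s2 * bases[[i]]))
      labs <- c(labs, sprintf("%s,scale=%g", labels[i], s2))
    }
  }
  dd <- dedupe_covariances(mats, labs)
  mats <- dd$matrices
  labs <- dd$labels
  if (include_null) {
    mats <- c(list(matrix(0, r, r)), mats)
    labs <- c("null", labs)
  }
  mixture_prior(mats, rep(1 / length(mats), length(mats)), labs)
}

#' Default scale grid for prior covariances
#'
#' Geometric-style grid of prior effect variances, relative to unit outcome
#' variance, spanning very small to large effects.
#' @return Numeric vector of scales.
#' @export
default_scale_grid <- function()
  c(0.01, 0.025, 0.05, 0.1, 0.2, 0.4, 0.8, 1.6)

#' Recipe describing how to build the prior covariance collection
#'
#' @param kind `"data_driven"` (default; competitive across sharing
#'   scenarios and fastest), `"canonical"`, or `"both"`.
#' @param scale_grid Strictly positive, sorted scale factors.
#' @param n_strong,n_pcs Passed to [data_driven_covariances()].
#' @param include_null Include the null component (default `TRUE`).
#' @return An object of class `"covariance_recipe"`.
#' @export
covariance_recipe <- function(kind = c("data_driven", "canonical", "both"),
                              scale_grid = default_scale_grid(),
                              n_strong = NULL, n_pcs = NULL,
                              include_null = TRUE) {
  kind <- match.arg(kind)
  if (any(scale_grid <= 0) || is.unsorted(scale_grid))
    stop("scale_grid must be strictly positive and sorted")
  structure(list(kind = kind, scale_grid = scale_grid, n_strong = n_strong,
                 n_pcs = n_pcs, include_null = include_null),
            class = "covariance_recipe")
}

#' Build a mixture prior from data according to a recipe
#'
#' Convenience wrapper: assembles canonical and/or data-driven covariance
#' bases, expands them over the scale grid and returns a [mixture_prior].
#'
#' @param X,Y Data matrices as in [data_driven_covariances()] (only needed
#'   for data-driven recipes).
#' @param r Number of conditions (only needed for purely canonical recipes
#'   when `Y` is not supplied).
#' @param recipe A [covariance_recipe].
#' @return A [mixture_prior].
#' @export
mr_mash_prior <- function(X = NULL, Y = NULL, r = NULL,
                          recipe = covariance_recipe()) {
  mats <- list()
  labs <- character(0)
  if (recipe$kind %in% c("canonical", "both")) {
    r_use <- r %||% ncol(as.matrix(Y))
    cc <- canonical_covariances(r_use)
    mats <- c(mats, cc$matrices)
    labs <- c(labs, cc$labels)
  }
  if (recipe$kind %in% c("data_driven", "both")) {
    dd <- data_driven_covariances(X, Y, n_strong = recipe$n_strong,
                                  n_pcs = recipe$n_pcs)
    mats <- c(mats, dd$matrices)
    labs <- c(labs, dd$labels)
  }
  expand_with_scale_grid(list(matrices = mats, labels = labs),
                         scale_grid = recipe$scale_grid,
                         include_null = recipe$include_null)
}

# Drop matrices equal entrywise (within 1e-12 on the largest entry) to an
# earlier one, keeping the first label.
dedupe_covariances <- function(mats, labs) {
  keep <- integer(0)
  for (i in seq_along(mats)) {
    dup <- FALSE
    for (j in keep) {
      tol <- 1e-12 * max(1, max(abs(mats[[j]])))
      if (identical(dim(mats[[i]]), dim(mats[[j]])) &&
          max(abs(mats[[i]] - mats[[j]])) <= tol) {
        dup <- TRUE
        break
      }
    }
    if (!dup) keep <- c(keep, i)
  }
  list(matrices = mats[keep], labels = labs[keep])
}
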