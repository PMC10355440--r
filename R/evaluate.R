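#' Standardized root mean squared prediction error
#'
#' RMSE divided by the standard deviation (sample, n-1 divisor) of the true
#' values in the test set, so a predictor with no signal scores 1 and the
#' metric is comparable across conditions with different variances.
#' Entries where either value is missing are excluded pairwise.
#'
#' @param y_true,y_pred Numeric vectors of equal length (at least 2
#'   complete pairs).
#' @return A single non-negative number.
#' @examples
#' standardized_rmse(c(0, 2), c(1, 1))  # 1 / sqrt(2)
#' @export
standardized_rmse <- function(y_true, y_pred) {
  y_true <- as.numeric(y_true)
  y_pred <- as.numeric(y_pred)
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have equal length")
  ok <- is.finite(y_true) & is.finite(y_pred)
  y_true <- y_true[ok]
  y_pred <- y_pred[ok]
  if (length(y_true) < 2)
    stop("need at least 2 complete (y_true, y_pred) pairs")
  s <- sd(y_true)
  if (s == 0)
    stop("standardized RMSE is undefined: sd(y_true) is zero")
  sqrt(mean((y_true - y_pred)^2)) / s
}

#' Relative difference in RMSE versus a reference method
#'
#' `(rmse_method - rmse_ref) / rmse_ref`; negative values mean the method
#' beats the reference.
#'
#' @param rmse_method,rmse_ref Non-negative RMSEs; `rmse_ref` must be
#'   positive.
#' @return A single number.
#' @export
relative_rmse <- function(rmse_method, rmse_ref) {
  if (any(rmse_ref <= 0))
    stop("rmse_ref must be positive")
  (rmse_method - rmse_ref) / rmse_ref
}

#' Per-condition prediction accuracy for one or more methods
#'
#' Computes the standardized RMSE of each method in each condition and,
#' when a reference method is named, the relative RMSE difference versus
#' it.
#'
#' @param Y_true m x r matrix of true test outcomes (may contain `NA`).
#' @param predictions Named list of m x r prediction matrices.
#' @param reference Optional name of the reference method in `predictions`.
#' @return A data frame with columns `condition`, `method`, `rmse`,
#'   `n_test`, and (with a reference) `relative_to_ref`.
#' @export
accuracy_table <- function(Y_true, predictions, reference = NULL) {
  Y_true <- as.matrix(Y_true)
  r <- ncol(Y_true)
  if (!is.list(predictions) || is.null(names(predictions)))
    stop("predictions must be a named list of matrices")
  if (!is.null(reference) && !reference %in% names(predictions))
    stop("reference method '", reference, "' is not among the predictions")
  conds <- colnames(Y_true) %||% paste0("condition_", seq_len(r))
  rows <- list()
  for (meth in names(predictions)) {
    P <- as.matrix(predictions[[meth]])
    if (!identical(dim(P), dim(Y_true)))
      stop("prediction matrix for '", meth, "' has wrong dimensions")
    for (s in seq_len(r)) {
      ok <- is.finite(Y_true[, s]) & is.finite(P[, s])
      rows[[length(rows) + 1L]] <- data.frame(
        condition = conds[s], method = meth,
        rmse = standardized_rmse(Y_true[ok, s], P[ok, s]),
        n_test = sum(ok))
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(reference)) {
    ref <- out[out$method == reference, c("condition", "rmse")]
    names(ref)[2L] <- "rmse_ref"
    out <- merge(out, ref, by = "condition", sort = FALSE)
    out$relative_to_ref <- relative_rmse(out$rmse, out$rmse_ref)
    out$rmse_ref <- NULL
  }
  out
}

#' Dominant effect-sharing pattern learned by one or more fits
#'
#' Identifies the non-null prior covariance component with the largest
#' estimated weight (summed across fits when a list is given) and rescales
#' it to a correlation matrix, `D^{-1/2} S0 D^{-1/2}` with `D = diag(S0)`.
#' Conditions with zero prior variance in the winning component are
#' reported as undefined: their rows and columns are `NA` and their indices
#' listed in `undefined_conditions`.
#'
#' @param fit A fitted [mr_mash] object, or a list of fits sharing the same
#'   prior component labels.
#' @return List with `correlation` (r x r), `label`, `weight` (total weight
#'   of the winning component) and `undefined_conditions`.
#' @export
report_top_pattern <- function(fit) {
  fits <- if (inherits(fit, "mr_mash")) list(fit) else fit
  if (!all(vapply(fits, inherits, logical(1), "mr_mash")))
    stop("fit must be an mr_mash object or a list of them")
  labels <- fits[[1L]]$prior$labels
  for (f in fits)
    if (!identical(f$prior$labels, labels))
      stop("all fits must share the same prior component labels")
  w <- Reduce(`+`, lapply(fits, function(f) f$prior$w0))
  nonnull <- which(vapply(fits[[1L]]$prior$S0,
                          function(m) any(m != 0), logical(1)))
  if (length(nonnull) == 0 || all(w[nonnull] == 0))
    stop("no non-null prior component has positive weight")
  k <- nonnull[which.max(w[nonnull])]
  S <- fits[[1L]]$prior$S0[[k]]
  d <- diag(S)
  undef <- which(d <= 0)
  ok <- which(d > 0)
  C <- matrix(NA_real_, nrow(S), ncol(S))
  Cd <- diag(1 / sqrt(d[ok]), length(ok))
  C[ok, ok] <- Cd %*% S[ok, ok, drop = FALSE] %*% Cd
  list(correlation = C, label = labels[k], weight = w[k],
       undefined_conditions = as.integer(undef))
}
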