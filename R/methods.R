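#' @export
print.mr_mash <- function(x, ...) {
  d <- x$dims
  cat(sprintf(
    "mr_mash fit: n = %d samples, p = %d predictors, r = %d conditions, K = %d prior components\n",
    d[["n"]], d[["p"]], d[["r"]], d[["K"]]))
  cat(sprintf("ELBO %.4f after %d iterations (%sconverged)\n",
              x$elbo_trace[x$n_iter], x$n_iter,
              if (x$converged) "" else "not "))
  nn <- if (x$prior$labels[1L] == "null") 1 - x$prior$w0[1L] else 1
  cat(sprintf("estimated non-null prior weight: %.3f\n", nn))
  invisible(x)
}

#' @export
summary.mr_mash <- function(object, ...) {
  w0 <- object$prior$w0
  ord <- order(w0, decreasing = TRUE)
  out <- list(
    dims = object$dims,
    elbo = object$elbo_trace[object$n_iter],
    n_iter = object$n_iter,
    converged = object$converged,
    top_components = data.frame(label = object$prior$labels[ord],
                                weight = w0[ord],
                                row.names = NULL)[w0[ord] > 0, ],
    V = object$V,
    pip = if ("null" %in% object$prior$labels)
      1 - object$W1[, match("null", object$prior$labels)]
    else rep(NA_real_, object$dims[["p"]]))
  class(out) <- "summary.mr_mash"
  out
}

#' @export
print.summary.mr_mash <- function(x, ...) {
  cat(sprintf(
    "mr_mash fit: n = %d, p = %d, r = %d, K = %d; ELBO %.4f (%d iterations, %sconverged)\n",
    x$dims[["n"]], x$dims[["p"]], x$dims[["r"]], x$dims[["K"]],
    x$elbo, x$n_iter, if (x$converged) "" else "not "))
  cat("\nPrior components with non-zero estimated weight (top 10):\n")
  print(utils::head(x$top_components, 10), digits = 4)
  if (!all(is.na(x$pip))) {
    cat(sprintf("\n%d of %d predictors have posterior non-null probability > 0.5\n",
                sum(x$pip > 0.5, na.rm = TRUE), length(x$pip)))
  }
  invisible(x)
}

#' Coefficients of a fitted model on the original predictor scale
#'
#' @param object A fitted [mr_mash] object.
#' @param ... Unused.
#' @return A (p + 1) x r matrix whose first row is the intercept and
#'   remaining rows the posterior-mean effects, on the scale of the
#'   predictors as supplied.
#' @export
coef.mr_mash <- function(object, ...) {
  B <- object$Bbar / object$scale
  b0 <- object$b0 - as.vector(crossprod(B, object$center))
  out <- rbind(`(Intercept)` = b0, B)
  colnames(out) <- object$condition_ids
  out
}

#' Predict outcomes for new samples
#'
#' Computes `Yhat = 1 b0' + X_new B` from the posterior-mean coefficients,
#' applying the centering/scaling stored in the fit so predictions are on
#' the original outcome scale.
#'
#' @param object A fitted [mr_mash] object.
#' @param newdata Numeric m x p matrix of predictors; defaults to the
#'   fitted values for the training data.  If both the fit and `newdata`
#'   carry predictor names they must match.
#' @param ... Unused.
#' @return An m x r matrix of predicted outcomes.
#' @export
predict.mr_mash <- function(object, newdata = NULL, ...) {
  if (is.null(newdata))
    return(fitted(object))
  Xn <- as.matrix(newdata)
  p <- object$dims[["p"]]
  if (ncol(Xn) != p)
    stop("newdata has ", ncol(Xn), " columns; the fit expects ", p)
  if (!is.null(colnames(Xn)) &&
      !identical(object$predictor_ids, paste0("predictor_", seq_len(p))) &&
      !identical(colnames(Xn), object$predictor_ids)) {
    missing_ids <- setdiff(object$predictor_ids, colnames(Xn))
    extra_ids <- setdiff(colnames(Xn), object$predictor_ids)
    stop("predictor ids do not match the fit; missing: [",
         paste(missing_ids, collapse = ", "), "], extra: [",
         paste(extra_ids, collapse = ", "), "]")
  }
  Xs <- sweep(sweep(Xn, 2L, object$center), 2L, object$scale, "/")
  out <- rep(object$b0, each = nrow(Xs)) + Xs %*% object$Bbar
  colnames(out) <- object$condition_ids
  out
}

#' @export
fitted.mr_mash <- function(object, ...) {
  out <- object$fitted_values
  colnames(out) <- object$condition_ids
  out
}

#' Residuals of a fitted model
#'
#' @param object A fitted [mr_mash] object.
#' @param ... Unused.
#' @return n x r matrix `Y_imputed - fitted(object)`; missing entries use
#'   their posterior-mean imputations.
#' @export
residuals.mr_mash <- function(object, ...) {
  object$Y_imputed - object$fitted_values
}

#' Plot the ELBO trace of a fit
#'
#' @param x A fitted [mr_mash] object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.mr_mash <- function(x, ...) {
  graphics::plot(seq_len(x$n_iter), x$elbo_trace, type = "b", pch = 20,
                 xlab = "iteration", ylab = "ELBO", ...)
  invisible(x)
}
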