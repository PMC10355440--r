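#' Bundle predictors and (possibly incomplete) outcomes for model fitting
#'
#' Light container pairing an n x p predictor matrix with an n x r outcome
#' matrix and an observation mask.  Predictors must be complete; outcomes may
#' contain missing entries, recorded either as `NA` in `Y` or as `FALSE` in
#' `mask`.  Validation enforces the shape contracts the fitting code relies
#' on: every sample retains at least one observed outcome, every condition
#' retains at least two, and constant predictor columns are flagged (in the
#' `"constant_predictors"` attribute) rather than silently dropped.
#'
#' @param X Numeric n x p predictor matrix (e.g. genotype dosages in 0-2).
#'   No missing values are allowed.
#' @param Y Numeric n x r outcome matrix; `NA` entries are treated as
#'   missing.
#' @param mask Optional n x r logical matrix, `TRUE` where `Y` is observed.
#'   Defaults to `!is.na(Y)`; where both are given, an entry is observed only
#'   if the mask is `TRUE` and the value is non-missing.
#' @param sample_ids,predictor_ids,condition_ids Optional character vectors
#'   of identifiers; default to the dimnames of `X` and `Y` or generated
#'   labels.
#'
#' @return An object of class `"regression_data"`: a list with elements
#'   `X`, `Y` (unobserved entries set to `NA`), `mask`, `sample_ids`,
#'   `predictor_ids`, `condition_ids`, with attribute
#'   `"constant_predictors"` giving indices of zero-variance columns of `X`.
#'
#' @examples
#' X <- matrix(rbinom(40, 2, 0.3), 10, 4)
#' Y <- matrix(rnorm(20), 10, 2)
#' Y[1, 2] <- NA
#' d <- regression_data(X, Y)
#' sum(d$mask)
#' @export
regression_data <- function(X, Y, mask = NULL, sample_ids = NULL,
                            predictor_ids = NULL, condition_ids = NULL) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  storage.mode(X) <- "double"
  storage.mode(Y) <- "double"
  if (nrow(X) != nrow(Y))
    stop("X and Y must have the same number of rows (samples); got ",
         nrow(X), " and ", nrow(Y))
  if (anyNA(X))
    stop("X must not contain missing values")
  if (is.null(mask)) {
    mask <- !is.na(Y)
  } else {
    mask <- as.matrix(mask)
    if (!identical(dim(mask), dim(Y)))
      stop("mask must have the same dimensions as Y")
    mask <- mask & !is.na(Y)
  }
  Y[!mask] <- NA
  if (any(rowSums(mask) < 1L))
    stop("every sample must have at least one observed outcome; offending ",
         "rows: ", paste(which(rowSums(mask) < 1L), collapse = ", "))
  if (any(colSums(mask) < 2L))
    stop("every condition must have at least two observed outcomes; ",
         "offending columns: ",
         paste(which(colSums(mask) < 2L), collapse = ", "))
  sample_ids <- sample_ids %||% rownames(X) %||%
    paste0("sample_", seq_len(nrow(X)))
  predictor_ids <- predictor_ids %||% colnames(X) %||%
    paste0("predictor_", seq_len(ncol(X)))
  condition_ids <- condition_ids %||% colnames(Y) %||%
    paste0("condition_", seq_len(ncol(Y)))
  if (length(sample_ids) != nrow(X) || length(predictor_ids) != ncol(X) ||
      length(condition_ids) != ncol(Y))
    stop("identifier lengths are inconsistent with the matrix dimensions")
  if (anyDuplicated(sample_ids) || anyDuplicated(predictor_ids) ||
      anyDuplicated(condition_ids))
    stop("identifiers must be unique")
  const <- which(apply(X, 2L, function(x) all(x == x[1L])))
  out <- structure(
    list(X = X, Y = Y, mask = mask, sample_ids = as.character(sample_ids),
         predictor_ids = as.character(predictor_ids),
         condition_ids = as.character(condition_ids)),
    class = "regression_data")
  attr(out, "constant_predictors") <- as.integer(const)
  out
}

#' @export
print.regression_data <- function(x, ...) {
  cat(sprintf(
    "regression_data: %d samples, %d predictors, %d conditions (%.1f%% of outcomes observed)\n",
    nrow(x$X), ncol(x$X), ncol(x$Y), 100 * mean(x$mask)))
  const <- attr(x, "constant_predictors")
  if (length(const) > 0)
    cat("constant predictor columns:", paste(const, collapse = ", "), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
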