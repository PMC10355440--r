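#' Read a delimited numeric matrix with identifiers
#'
#' Reads a TSV (or CSV) file whose header row names the columns and whose
#' first column holds row identifiers.  `"NA"` or empty cells denote
#' missing values and are only permitted when `missing_ok = TRUE` (outcome
#' matrices); predictor matrices must be complete.  Writing with
#' [write_matrix()] and reading back is lossless.
#'
#' @param path File path.
#' @param missing_ok Allow missing cells (default `FALSE`).
#' @param sep Field separator (default tab).
#' @return Numeric matrix with row and column names.
#' @export
read_matrix <- function(path, missing_ok = FALSE, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  nf <- count.fields(path, sep = sep, quote = "\"", comment.char = "")
  if (length(unique(nf)) > 1) {
    bad <- which(nf != nf[1L])
    stop("ragged rows in ", path, " at line(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  df <- read.delim(path, sep = sep, check.names = FALSE,
                   stringsAsFactors = FALSE, na.strings = c("NA", ""))
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate row identifiers in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (!missing_ok && anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)[1L, ]
    stop("missing cell not allowed in ", path, ": row '",
         ids[idx[1L]], "' (line ", idx[1L] + 1L, "), column '",
         colnames(m)[idx[2L]], "'")
  }
  m
}

#' Write a numeric matrix as TSV with identifiers
#'
#' Values are written with 17 significant digits so a write/read round trip
#' reproduces them exactly; missing entries are written as `NA`.
#'
#' @param x Numeric matrix (row/column names used as identifiers; generated
#'   if absent).
#' @param path Output file path.
#' @param id_name Header of the identifier column (default `"id"`).
#' @param sep Field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path, id_name = "id", sep = "\t") {
  x <- as.matrix(x)
  rn <- rownames(x) %||% paste0("row_", seq_len(nrow(x)))
  cn <- colnames(x) %||% paste0("col_", seq_len(ncol(x)))
  fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.17g", v))
  lines <- c(paste(c(id_name, cn), collapse = sep),
             vapply(seq_len(nrow(x)), function(i)
               paste(c(rn[i], fmt(x[i, ])), collapse = sep), character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Serialize a mixture prior to a directory
#'
#' Writes one labeled TSV per covariance component plus a JSON manifest
#' (labels, weights, dimension, file order).
#'
#' @param prior A [mixture_prior].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_mixture_prior <- function(prior, dir) {
  stopifnot(inherits(prior, "mixture_prior"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("S0_%03d.tsv", seq_len(prior$K))
  for (k in seq_len(prior$K)) {
    m <- prior$S0[[k]]
    dimnames(m) <- list(paste0("c", seq_len(prior$r)),
                        paste0("c", seq_len(prior$r)))
    write_matrix(m, file.path(dir, files[k]))
  }
  manifest <- list(type = "mixture_prior", r = prior$r, K = prior$K,
                   labels = prior$labels, w0 = prior$w0, files = files)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Load a mixture prior saved by [save_mixture_prior()]
#' @param dir Directory containing `manifest.json` and component TSVs.
#' @return A [mixture_prior].
#' @export
load_mixture_prior <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  S0 <- lapply(man$files, function(f) {
    m <- read_matrix(file.path(dir, f))
    dimnames(m) <- NULL
    m
  })
  mixture_prior(S0, man$w0, man$labels)
}

#' Serialize a fitted model to a directory bundle
#'
#' Writes the intercept, coefficients, residual covariance, estimated prior
#' weights, ELBO trace and the prior itself as delimited text plus a JSON
#' manifest, so a fit round-trips exactly ([load_mr_mash_fit()]) and two
#' fits of identical data and options produce byte-identical bundles.
#'
#' @param fit A fitted [mr_mash] object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_mr_mash_fit <- function(fit, dir) {
  stopifnot(inherits(fit, "mr_mash"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  conds <- fit$condition_ids
  b0 <- matrix(fit$b0, 1L, dimnames = list("b0", conds))
  write_matrix(b0, file.path(dir, "b0.tsv"))
  write_matrix(fit$Bbar, file.path(dir, "Bbar.tsv"))
  V <- fit$V
  dimnames(V) <- list(conds, conds)
  write_matrix(V, file.path(dir, "V.tsv"))
  w0 <- matrix(fit$prior$w0, ncol = 1L,
               dimnames = list(fit$prior$labels, "w0"))
  write_matrix(w0, file.path(dir, "w0.tsv"), id_name = "component")
  elbo <- matrix(fit$elbo_trace, ncol = 1L,
                 dimnames = list(seq_along(fit$elbo_trace), "elbo"))
  write_matrix(elbo, file.path(dir, "elbo.tsv"), id_name = "iteration")
  cs <- rbind(center = fit$center, scale = fit$scale)
  colnames(cs) <- fit$predictor_ids
  write_matrix(cs, file.path(dir, "standardization.tsv"))
  save_mixture_prior(fit$prior, file.path(dir, "prior"))
  manifest <- list(type = "mr_mash_fit",
                   package_version = as.character(packageVersion("mvmash")),
                   dims = as.list(fit$dims),
                   n_iter = fit$n_iter, converged = fit$converged,
                   intercept = fit$intercept, standardize = fit$standardize,
                   options = fit$options,
                   predictor_ids = fit$predictor_ids,
                   condition_ids = fit$condition_ids)
  jsonlite::write_json(manifest, file.path(dir, "fit.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Load a fitted-model bundle saved by [save_mr_mash_fit()]
#'
#' Reconstructs an `mr_mash` object sufficient for prediction and
#' reporting (posterior-per-predictor reconstruction requires the original
#' in-memory fit).
#'
#' @param dir Bundle directory.
#' @return An object of class `"mr_mash"`.
#' @export
load_mr_mash_fit <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "fit.json"),
                             simplifyVector = TRUE)
  Bbar <- read_matrix(file.path(dir, "Bbar.tsv"))
  b0 <- drop(read_matrix(file.path(dir, "b0.tsv")))
  V <- read_matrix(file.path(dir, "V.tsv"))
  dimnames(V) <- NULL
  cs <- read_matrix(file.path(dir, "standardization.tsv"))
  elbo <- drop(read_matrix(file.path(dir, "elbo.tsv")))
  prior <- load_mixture_prior(file.path(dir, "prior"))
  prior$w0 <- drop(read_matrix(file.path(dir, "w0.tsv")))
  names(prior$w0) <- NULL
  structure(list(
    b0 = b0, Bbar = Bbar, V = V, prior = prior,
    W1 = NULL, Bhat = NULL, xtx = NULL,
    elbo_trace = as.numeric(elbo), n_iter = man$n_iter,
    converged = man$converged, Y_imputed = NULL, fitted_values = NULL,
    center = unname(cs["center", ]), scale = unname(cs["scale", ]),
    intercept = man$intercept, standardize = man$standardize,
    dims = unlist(man$dims), predictor_ids = man$predictor_ids,
    condition_ids = man$condition_ids, options = man$options,
    call = NULL), class = "mr_mash")
}
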