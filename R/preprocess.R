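# Count filtering, library-size normalization and covariate residualization.

#' Filter lowly expressed features
#'
#' Keeps features with overall mean expression strictly greater than
#' `min_mean` reads and a nonzero count in at least `min_prop` of the samples.
#'
#' @param counts features x samples non-negative integer matrix.
#' @param min_mean minimum mean read count (strict inequality); default 15.
#' @param min_prop minimum fraction of samples with a nonzero count
#'   (inclusive); default 0.05.
#' @return the filtered count matrix; the number of removed features is
#'   reported via `message()`.
#' @export
filter_features <- function(counts, min_mean = 15, min_prop = 0.05) {
  check_count_matrix(counts)
  keep <- rowMeans(counts) > min_mean &
    rowMeans(counts > 0) >= min_prop
  if (!any(keep))
    stop_mv("no feature passes the expression filter; lower min_mean/min_prop")
  message(sprintf("filter_features: removed %d of %d features",
                  sum(!keep), nrow(counts)))
  counts[keep, , drop = FALSE]
}

#' Median-of-ratios size factors
#'
#' Size factor of sample j is the median across features of the ratio of its
#' count to the per-feature geometric mean, restricted to features nonzero in
#' every sample (the usual median-of-ratios estimator). When no feature is
#' expressed in all samples the total-count factors (rescaled to geometric
#' mean 1) are used instead, with a warning.
#'
#' @param counts filtered features x samples count matrix.
#' @return numeric vector of per-sample size factors.
#' @export
size_factors <- function(counts) {
  allpos <- rowSums(counts == 0) == 0
  if (!any(allpos)) {
    warning("no feature nonzero in all samples; using total-count size factors")
    s <- colSums(counts)
    return(s / exp(mean(log(s))))
  }
  ref <- exp(rowMeans(log(counts[allpos, , drop = FALSE])))
  apply(counts[allpos, , drop = FALSE] / ref, 2, stats::median)
}

#' Normalize counts to a log2 expression matrix
#'
#' Divides each sample by its median-of-ratios size factor and log-transforms:
#' value = log2(count / s_j + 1). This meets the two goals of library-size
#' normalization and variance-reducing log transformation with a fully
#' specified algorithm.
#'
#' @param counts filtered count matrix (features x samples).
#' @return ExprMatrix: numeric matrix with dimnames preserved and the size
#'   factors in `attr(, "size_factors")`.
#' @export
normalize_counts <- function(counts) {
  check_count_matrix(counts)
  if (any(colSums(counts) == 0)) stop_mv("a sample has all-zero counts")
  s <- size_factors(counts)
  out <- log2(sweep(counts, 2, s, "/") + 1)
  attr(out, "size_factors") <- s
  out
}

#' Residualize expression on covariates
#'
#' Per-feature ordinary least squares of expression on the covariate design
#' (with intercept); returns the residual matrix. Used to remove sequencing
#' batch before network construction and batch/technical covariates before
#' integration analyses.
#'
#' @param expr features x samples numeric matrix.
#' @param covariates data.frame of per-sample covariates (factors/characters
#'   are expanded to indicators); rows must align with `expr` columns.
#' @return residual matrix, mean 0 per feature, same dimnames.
#' @export
residualize <- function(expr, covariates) {
  if (ncol(expr) != nrow(covariates))
    stop_mv("covariate rows (%d) do not match samples (%d)",
            nrow(covariates), ncol(expr))
  covariates <- as.data.frame(covariates)
  for (j in seq_along(covariates))
    if (is.character(covariates[[j]])) covariates[[j]] <- factor(covariates[[j]])
  # drop single-level factors (e.g. one batch) -> intercept-only centering
  keep <- vapply(covariates, function(v) length(unique(v)) > 1, logical(1))
  X <- if (any(keep)) {
    stats::model.matrix(~., data = covariates[, keep, drop = FALSE])
  } else matrix(1, nrow(covariates), 1, dimnames = list(NULL, "(Intercept)"))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop_mv("rank-deficient covariate design; collinear columns: %s",
            paste(bad, collapse = ", "))
  }
  res <- t(qr.resid(qrX, t(expr)))
  dimnames(res) <- dimnames(expr)
  res
}

check_count_matrix <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop_mv("counts must be a numeric matrix")
  bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad)) {
    stop_mv("non-integer or negative count at feature '%s', sample '%s'",
            rownames(counts)[bad[1, 1]] %||% bad[1, 1],
            colnames(counts)[bad[1, 2]] %||% bad[1, 2])
  }
  invisible(counts)
}
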