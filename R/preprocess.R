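# Preprocessing to the centralized log10 scale the map training assumes:
# log10-transform, quantile normalization across samples, and per-gene
# centralization (row mean zero). Positive centralized values read as
# over-expression, negative ones as under-expression.

#' Log10-transform an expression matrix
#'
#' @param x Numeric matrix (genes x samples) of raw intensities, or a
#'   `SummarizedExperiment`.
#' @param offset Nonnegative value added before taking logs (default 0).
#' @return Matrix of `log10(x + offset)` values.
#' @export
log10Transform <- function(x, offset = 0) {
  m <- .getExprs(x)
  bad <- which(m + offset <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    g <- if (is.null(rownames(m))) bad[1L, 1L] else rownames(m)[bad[1L, 1L]]
    s <- if (is.null(colnames(m))) bad[1L, 2L] else colnames(m)[bad[1L, 2L]]
    stop("nonpositive value + offset at gene ", g, ", sample ", s,
         "; increase `offset`")
  }
  log10(m + offset)
}

#' Quantile-normalize an expression matrix
#'
#' Forces every sample (column) onto one common distribution: after
#' normalization the sorted values of all columns equal the cross-column
#' rank means. Ties within a column receive the mean of the reference
#' values at their tied ranks.
#'
#' @param x Numeric matrix (genes x samples) or `SummarizedExperiment`.
#' @return Normalized matrix of the same shape.
#' @export
quantileNormalize <- function(x) {
  m <- .getExprs(x)
  if (ncol(m) < 2L) stop("quantile normalization needs at least 2 samples")
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' Centralize an expression matrix
#'
#' Subtracts each gene's mean log-expression across all samples, so every
#' row has zero mean and values read as over-/under-expression relative to
#' the cohort average.
#'
#' @param x Numeric matrix (genes x samples) or `SummarizedExperiment`.
#' @return Centralized matrix.
#' @export
centralize <- function(x) {
  m <- .getExprs(x)
  m - rowMeans(m)
}

#' Run the full preprocessing chain
#'
#' `log10Transform` then `quantileNormalize` then `centralize`, with skip
#' flags for inputs that are already log-scaled and/or normalized (the
#' usual situation for preprocessed repository data).
#'
#' @param x Numeric matrix (genes x samples) or `SummarizedExperiment`.
#' @param log10 Apply the log10 transform?
#' @param qnorm Apply quantile normalization?
#' @param offset Offset for the log10 transform.
#' @return Centralized matrix.
#' @export
preprocessExpression <- function(x, log10 = TRUE, qnorm = TRUE, offset = 0) {
  m <- .getExprs(x)
  if (anyNA(m)) stop("missing values are not permitted")
  if (log10) m <- log10Transform(m, offset = offset)
  if (qnorm) m <- quantileNormalize(m)
  centralize(m)
}
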