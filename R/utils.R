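# Grid indexing helpers. Pixels are addressed as (col, row), both 0-based,
# origin top-left; the linear index is row-major: index = row * width + col
# (converted to 1-based for R vectors).

#' Convert (col, row) pixel coordinates to 1-based linear indices
#'
#' @param col,row 0-based pixel coordinates.
#' @param width Grid width in pixels.
#' @return 1-based linear indices into a map vector.
#' @export
pixelIndex <- function(col, row, width) {
  stopifnot(all(col >= 0), all(row >= 0), all(col < width))
  as.integer(row * width + col + 1L)
}

#' Convert 1-based linear indices back to (col, row) coordinates
#'
#' @param index 1-based linear indices.
#' @param width Grid width in pixels.
#' @return Integer matrix with columns `col` and `row` (0-based).
#' @export
pixelCoords <- function(index, width) {
  i0 <- as.integer(index) - 1L
  cbind(col = i0 %% as.integer(width), row = i0 %/% as.integer(width))
}

# (col,row) coordinates of all grid units in linear order
.gridCoords <- function(width, height) {
  cbind(col = rep(seq_len(width) - 1L, times = height),
        row = rep(seq_len(height) - 1L, each = width))
}

.isCount <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 1 && x == round(x)
}

.getExprs <- function(x) {
  if (methods::is(x, "SummarizedExperiment")) {
    return(SummarizedExperiment::assay(x))
  }
  if (!is.matrix(x)) stop("expected a matrix or SummarizedExperiment")
  x
}

# Mann-Whitney AUC of `scores` for separating `positive` (logical) from the
# rest; mid-ranks handle ties, so tied pairs count 1/2.
.rankAUC <- function(scores, positive) {
  np <- sum(positive)
  nn <- sum(!positive)
  if (np == 0L || nn == 0L) {
    stop("AUC needs both a positive and a negative class")
  }
  r <- rank(scores)
  (sum(r[positive]) - np * (np + 1) / 2) / (np * nn)
}

.checkSampleIDs <- function(ids, where) {
  if (anyNA(ids) || any(ids == "")) stop("missing sample IDs in ", where)
  if (anyDuplicated(ids)) {
    stop("duplicate sample IDs in ", where, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  invisible(TRUE)
}
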