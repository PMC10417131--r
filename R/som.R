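# Batch self-organizing map on a planar rectangular grid.
#
# Each gene's expression profile (its row of the centralized matrix) is a
# point in sample space; the map places similar profiles on nearby grid
# units so that co-expressed gene modules appear as contiguous spots.
# Training is the classic batch scheme: all genes are assigned to their
# best-matching unit (BMU, Euclidean distance, ties to the lowest linear
# index), then every prototype is replaced by the neighborhood-weighted
# mean of the assigned profiles. The Gaussian neighborhood radius anneals
# linearly from gridWidth/2 to 1; prototypes are initialized on the plane
# spanned by the first two principal components of the gene cloud.
#
# The Gaussian kernel on the grid factorizes over the column and row
# coordinates, so the neighborhood smoothing is applied as two small 1-D
# kernel multiplications instead of a (width*height)^2 product.

.somSmooth <- function(m, kCol, kRow, width, height) {
  # m: (width*height) x k in row-major linear order -> array dim (width, height)
  k <- ncol(m)
  a <- array(m, dim = c(width, height, k))
  out <- vapply(seq_len(k), function(j) kCol %*% a[, , j] %*% kRow,
                matrix(0, width, height))
  matrix(out, width * height, k)
}

.bmu <- function(x, w) {
  # x: genes x samples, w: units x samples; returns per-gene BMU index and
  # squared distance. argmin_u |x - w_u|^2 = argmax_u (x.w_u - |w_u|^2/2)
  score <- tcrossprod(x, w)
  half <- 0.5 * rowSums(w * w)
  score <- sweep(score, 2L, half)
  bmu <- max.col(score, ties.method = "first")
  d2 <- rowSums(x * x) - 2 * score[cbind(seq_len(nrow(x)), bmu)]
  list(bmu = bmu, d2 = pmax(d2, 0))
}

#' Train a self-organizing map of metagenes
#'
#' @param x Centralized expression matrix (genes x samples) or a
#'   `SummarizedExperiment`. Rows are the profiles being clustered.
#' @param gridWidth,gridHeight Grid dimensions in pixels (default 50 x 50,
#'   i.e. 2500 metagenes).
#' @param epochs Number of batch sweeps (default 30).
#' @param seed Integer seed (principal-component signs and any downstream
#'   stochastic consumers); training itself is deterministic given the
#'   initialization.
#' @param radiusInitial,radiusFinal Gaussian neighborhood radius at the
#'   first and last epoch; annealed linearly in between.
#' @return A [SOMModel-class] with prototypes (metagene profiles), the
#'   gene-to-metagene assignment and the per-epoch quantization-error
#'   trace.
#' @examples
#' x <- matrix(rnorm(200 * 10), 200, 10,
#'             dimnames = list(sprintf("g%03d", 1:200), sprintf("s%02d", 1:10)))
#' model <- trainSOM(centralize(x), gridWidth = 6, gridHeight = 6,
#'                   epochs = 5, seed = 1)
#' nMetagenes(model)
#' @export
trainSOM <- function(x, gridWidth = 50, gridHeight = 50, epochs = 30,
                     seed = 1L, radiusInitial = max(gridWidth, gridHeight) / 2,
                     radiusFinal = 1) {
  m <- .getExprs(x)
  if (nrow(m) == 0L || ncol(m) == 0L) stop("empty expression matrix")
  if (is.null(rownames(m))) rownames(m) <- sprintf("gene%05d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("sample%03d", seq_len(ncol(m)))
  stopifnot(.isCount(gridWidth), .isCount(gridHeight), .isCount(epochs))
  gridWidth <- as.integer(gridWidth)
  gridHeight <- as.integer(gridHeight)
  nU <- gridWidth * gridHeight
  if (nU > nrow(m)) {
    warning("more grid cells (", nU, ") than genes (", nrow(m), ")")
  }
  if (max(abs(rowMeans(m))) > 1e-6) {
    warning("input rows are not centralized; consider centralize()")
  }
  set.seed(seed)

  # linear initialization on the first two principal components
  w <- .somInit(m, gridWidth, gridHeight)

  radius <- if (epochs == 1L) radiusFinal else {
    seq(radiusInitial, radiusFinal, length.out = epochs)
  }
  qe <- numeric(epochs)
  cc <- seq_len(gridWidth) - 1L
  rr <- seq_len(gridHeight) - 1L
  for (e in seq_len(epochs)) {
    hit <- .bmu(m, w)
    qe[e] <- mean(sqrt(hit$d2))
    sg <- radius[e]
    kCol <- exp(-outer(cc, cc, "-")^2 / (2 * sg^2))
    kRow <- exp(-outer(rr, rr, "-")^2 / (2 * sg^2))
    sums <- rowsum(m, hit$bmu)
    full <- matrix(0, nU, ncol(m))
    full[as.integer(rownames(sums)), ] <- sums
    cnt <- tabulate(hit$bmu, nU)
    num <- .somSmooth(full, kCol, kRow, gridWidth, gridHeight)
    den <- as.vector(.somSmooth(matrix(cnt), kCol, kRow, gridWidth, gridHeight))
    w <- num / den
  }
  final <- .bmu(m, w)
  colnames(w) <- colnames(m)
  methods::new("SOMModel",
    gridWidth = gridWidth, gridHeight = gridHeight,
    prototypes = w,
    assignment = stats::setNames(as.integer(final$bmu), rownames(m)),
    epochs = as.integer(epochs),
    radiusSchedule = radius,
    seed = as.integer(seed),
    qe = qe)
}

.somInit <- function(m, gridWidth, gridHeight) {
  nU <- gridWidth * gridHeight
  ctr <- colMeans(m)
  w <- matrix(rep(ctr, each = nU), nU, ncol(m))
  if (gridWidth > 1L || gridHeight > 1L) {
    pc <- tryCatch(stats::prcomp(m, rank. = 2L, center = TRUE),
                   error = function(e) NULL)
    if (!is.null(pc) && ncol(pc$rotation) >= 1L) {
      coords <- .gridCoords(gridWidth, gridHeight)
      u1 <- if (gridWidth > 1L) {
        2 * (coords[, "col"] / (gridWidth - 1L)) - 1
      } else rep(0, nU)
      u2 <- if (gridHeight > 1L) {
        2 * (coords[, "row"] / (gridHeight - 1L)) - 1
      } else rep(0, nU)
      s1 <- stats::sd(pc$x[, 1L])
      w <- w + 2 * s1 * tcrossprod(u1, pc$rotation[, 1L])
      if (ncol(pc$rotation) >= 2L) {
        s2 <- stats::sd(pc$x[, 2L])
        w <- w + 2 * s2 * tcrossprod(u2, pc$rotation[, 2L])
      }
    }
  }
  w
}
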