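# Per-sample portraits, group mean/difference portraits, supporting maps,
# silhouette diagnostics and low-dimensional sample embeddings.
#
# Maps and portraits are numeric vectors of length width*height in the
# documented row-major linear pixel order; portraitMatrix() reshapes them
# into a height x width image for display.

#' Per-sample expression portrait
#'
#' The portrait of a sample is its column of the prototype matrix: the
#' value at pixel p is that metagene's expression in the sample.
#'
#' @param model A [SOMModel-class].
#' @param sample Sample ID (or column index).
#' @return Numeric vector of length width*height (linear pixel order).
#' @export
portrait <- function(model, sample) {
  stopifnot(methods::is(model, "SOMModel"))
  if (is.character(sample) && !sample %in% sampleIDs(model)) {
    stop("unknown sample: ", sample)
  }
  model@prototypes[, sample]
}

#' Reshape a map vector into an image matrix
#'
#' @param map Numeric vector in linear pixel order.
#' @param model The `SOMModel` supplying the grid dimensions.
#' @return A `height x width` matrix; `[row + 1, col + 1]` holds pixel
#'   `(col, row)`.
#' @export
portraitMatrix <- function(map, model) {
  stopifnot(length(map) == nMetagenes(model))
  t(matrix(map, model@gridWidth, model@gridHeight))
}

#' Group mean portrait
#'
#' @param model A `SOMModel`.
#' @param samples Nonempty character vector of sample IDs.
#' @return Pixelwise mean portrait (linear order).
#' @export
groupMeanPortrait <- function(model, samples) {
  stopifnot(methods::is(model, "SOMModel"))
  if (length(samples) == 0L) stop("empty sample group")
  missing <- setdiff(samples, sampleIDs(model))
  if (length(missing)) {
    stop("unknown samples: ", paste(missing, collapse = ", "))
  }
  rowMeans(model@prototypes[, samples, drop = FALSE])
}

#' Difference portrait between two groups
#'
#' @param model A `SOMModel`.
#' @param groupA,groupB Nonempty character vectors of sample IDs.
#' @return Pixelwise `mean(A) - mean(B)` portrait.
#' @export
differencePortrait <- function(model, groupA, groupB) {
  groupMeanPortrait(model, groupA) - groupMeanPortrait(model, groupB)
}

#' Supporting maps of a trained model
#'
#' Variance map (per-metagene variance across samples), population map
#' (genes per metagene), group summary map (pixelwise maximum over group
#' mean portraits) and personalized summary map (pixelwise q-quantile over
#' all individual portraits; the default q = 0.9 highlights spots that are
#' strong in at least a tenth of the samples, independent of grouping).
#'
#' @param model A `SOMModel`.
#' @param groups Optional named factor/character of group labels per
#'   sample (names = sample IDs) for the group summary map.
#' @param q Quantile for the personalized summary map, in (0, 1).
#' @return List with `variance`, `population`, `groupSummary` (NULL
#'   without groups) and `personalizedSummary`, all in linear pixel order.
#' @export
supportingMaps <- function(model, groups = NULL, q = 0.9) {
  stopifnot(methods::is(model, "SOMModel"))
  if (q <= 0 || q >= 1) stop("q must be inside (0, 1)")
  w <- model@prototypes
  varianceMap <- apply(w, 1L, stats::var)
  populationMap <- tabulate(model@assignment, nMetagenes(model))
  groupSummary <- NULL
  if (!is.null(groups)) {
    if (is.null(names(groups))) {
      stopifnot(length(groups) == ncol(w))
      names(groups) <- colnames(w)
    }
    means <- vapply(split(names(groups), as.character(groups)),
                    function(s) groupMeanPortrait(model, s),
                    numeric(nrow(w)))
    groupSummary <- apply(means, 1L, max)
  }
  personalized <- apply(w, 1L, stats::quantile, probs = q, names = FALSE)
  list(variance = varianceMap, population = populationMap,
       groupSummary = groupSummary, personalizedSummary = personalized)
}

#' Silhouette scores of samples within subtype clusters
#'
#' Distance between samples is 1 - Pearson correlation of their metagene
#' profiles (portraits). Singleton clusters score 0 by convention; the
#' reported neighbor is the foreign cluster with the smallest mean
#' distance.
#'
#' @param model A `SOMModel`.
#' @param labels Cluster (subtype) label per sample, named by sample ID or
#'   aligned with the model's sample order.
#' @return `data.frame` with columns `sample`, `cluster`, `neighbor`,
#'   `silhouette`.
#' @export
silhouetteScores <- function(model, labels) {
  stopifnot(methods::is(model, "SOMModel"))
  w <- model@prototypes
  labels <- .alignLabels(labels, colnames(w))
  f <- factor(labels)
  if (nlevels(f) < 2L) stop("silhouette needs at least 2 clusters")
  d <- stats::as.dist(1 - stats::cor(w))
  sil <- cluster::silhouette(as.integer(f), d)
  data.frame(
    sample = colnames(w),
    cluster = levels(f)[sil[, "cluster"]],
    neighbor = levels(f)[sil[, "neighbor"]],
    silhouette = sil[, "sil_width"],
    stringsAsFactors = FALSE
  )
}

.alignLabels <- function(labels, ids) {
  if (!is.null(names(labels))) {
    missing <- setdiff(ids, names(labels))
    if (length(missing)) {
      stop("labels missing for samples: ", paste(missing, collapse = ", "))
    }
    labels <- labels[ids]
  } else if (length(labels) != length(ids)) {
    stop("labels must be named or match the number of samples")
  }
  as.character(labels)
}

#' Embed samples in low dimension
#'
#' Independent component analysis (FastICA fixed-point iteration on
#' PCA-whitened metagene profiles) or a sample correlation network.
#' Zero-variance metagenes are dropped before embedding.
#'
#' @param model A `SOMModel`.
#' @param method `"ica"` or `"network"`.
#' @param k Number of components (ica).
#' @param seed Integer seed for the ICA initialization.
#' @param corThreshold Correlation threshold for network edges.
#' @return For `"ica"`, a samples x k coordinate matrix; for
#'   `"network"`, a list with the `igraph` graph and the correlation
#'   matrix.
#' @export
embedSamples <- function(model, method = c("ica", "network"), k = 2,
                         seed = 1L, corThreshold = 0.5) {
  stopifnot(methods::is(model, "SOMModel"))
  method <- match.arg(method)
  w <- model@prototypes
  keep <- apply(w, 1L, stats::var) > 0
  w <- w[keep, , drop = FALSE]
  if (method == "network") {
    cc <- stats::cor(w)
    adj <- cc > corThreshold
    diag(adj) <- FALSE
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    return(list(graph = g, correlation = cc))
  }
  n <- ncol(w)
  if (k > n - 1L) stop("k must be at most n_samples - 1")
  z <- t(w)                       # samples x metagenes
  z <- scale(z, center = TRUE, scale = FALSE)
  pc <- stats::prcomp(z, rank. = k, center = FALSE)
  white <- sweep(pc$x, 2L, pc$sdev[seq_len(k)], "/")  # samples x k, unit var
  set.seed(seed)
  s <- .fastICA(white, k)
  rownames(s) <- colnames(model@prototypes)
  s
}

# Symmetric FastICA with the logcosh contrast on pre-whitened data
# (rows = observations, columns = whitened components).
.fastICA <- function(z, k, maxit = 200L, tol = 1e-7) {
  n <- nrow(z)
  W <- matrix(stats::rnorm(k * k), k, k)
  W <- .orthonormalize(W)
  for (it in seq_len(maxit)) {
    wx <- z %*% t(W)              # n x k
    gwx <- tanh(wx)
    gpr <- colMeans(1 - gwx^2)
    W1 <- crossprod(gwx, z) / n - diag(gpr, k) %*% W
    W1 <- .orthonormalize(W1)
    delta <- max(abs(abs(rowSums(W1 * W)) - 1))
    W <- W1
    if (delta < tol) break
  }
  z %*% t(W)
}

.orthonormalize <- function(W) {
  s <- svd(W)
  s$u %*% t(s$v)
}
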