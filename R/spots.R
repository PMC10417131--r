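# Overexpression spot modules: detection on summary maps by percentile
# thresholding and 8-connected component labeling, spot expression
# profiles, per-portrait spot counts, one-vs-rest ROC/AUC, ternary
# combinations, signed weighted topological overlap between spots, and the
# liver-contamination two-group split.

# 8-connected component labeling on a width x height grid; mask is a
# logical vector in linear pixel order. Returns integer labels (0 outside
# the mask).
.labelComponents <- function(mask, width, height) {
  labels <- integer(length(mask))
  nextLab <- 0L
  for (start in which(mask)) {
    if (labels[start] != 0L) next
    nextLab <- nextLab + 1L
    queue <- start
    labels[start] <- nextLab
    while (length(queue)) {
      p <- queue[[1L]]
      queue <- queue[-1L]
      p0 <- p - 1L
      pc <- p0 %% width
      pr <- p0 %/% width
      for (dc in -1:1) for (dr in -1:1) {
        if (dc == 0L && dr == 0L) next
        nc <- pc + dc; nr <- pr + dr
        if (nc < 0L || nr < 0L || nc >= width || nr >= height) next
        q <- nr * width + nc + 1L
        if (mask[q] && labels[q] == 0L) {
          labels[q] <- nextLab
          queue <- c(queue, q)
        }
      }
    }
  }
  labels
}

#' Detect overexpression spots on a summary map
#'
#' Pixels above the per-map threshold percentile form the overexpression
#' relief; within it, spots are separated by grayscale watershed
#' segmentation (`EBImage::watershed`) so that neighboring modules whose
#' flanks touch above the threshold are split at their saddle instead of
#' merging. The `tolerance` (in map units, i.e. centralized log10
#' expression) is the minimum height of a local peak above a saddle for
#' it to count as a separate spot; `tolerance = Inf` disables the split
#' and reduces the rule to plain 8-connected component labeling above the
#' threshold. Components smaller than `minPixels` are dropped; surviving
#' spots are labeled "A", "B", ... in descending order of their peak map
#' value. A spot's gene list contains the genes whose best-matching unit
#' lies inside its pixel set, and its per-sample profile is the mean
#' metagene expression over the pixel set.
#'
#' @param model A [SOMModel-class].
#' @param map Summary map (linear pixel order), e.g. from
#'   [supportingMaps()].
#' @param thresholdQuantile Per-map detection percentile (default 0.82).
#' @param tolerance Watershed merge tolerance in map units (default
#'   0.1).
#' @param minPixels Minimum component size in pixels (default 4).
#' @return A [SpotCollection-class] (possibly empty).
#' @export
detectSpots <- function(model, map, thresholdQuantile = 0.82,
                        tolerance = 0.1, minPixels = 4) {
  stopifnot(methods::is(model, "SOMModel"),
            length(map) == nMetagenes(model))
  thr <- stats::quantile(map, thresholdQuantile, names = FALSE)
  comps <- .spotComponents(map, model@gridWidth, model@gridHeight,
                           thr, minPixels, tolerance)
  if (length(comps) == 0L) {
    message("no spots survive the detection threshold")
  }
  labels <- if (length(comps)) LETTERS[seq_along(comps)] else character(0)
  if (length(comps) > 26L) {
    labels <- c(LETTERS, paste0("A", LETTERS))[seq_along(comps)]
  }
  genes <- lapply(comps, function(px) {
    names(model@assignment)[model@assignment %in% px]
  })
  profiles <- if (length(comps)) {
    t(vapply(comps, function(px) {
      colMeans(model@prototypes[px, , drop = FALSE])
    }, numeric(ncol(model@prototypes))))
  } else {
    matrix(0, 0, ncol(model@prototypes))
  }
  rownames(profiles) <- labels
  colnames(profiles) <- sampleIDs(model)
  methods::new("SpotCollection",
    labels = labels, pixels = comps, genes = genes, profiles = profiles,
    map = as.numeric(map), gridWidth = model@gridWidth,
    gridHeight = model@gridHeight, threshold = thr,
    minPixels = as.integer(minPixels))
}

.spotComponents <- function(map, width, height, threshold, minPixels,
                            tolerance = Inf) {
  mask <- map > threshold
  if (!any(mask)) return(list())
  if (is.finite(tolerance)) {
    relief <- matrix(pmax(map - threshold, 0), width, height)
    ws <- EBImage::watershed(EBImage::as.Image(relief),
                             tolerance = tolerance, ext = 1)
    labels <- as.integer(as.vector(EBImage::imageData(ws)))
    labels[!mask] <- 0L
  } else {
    labels <- .labelComponents(mask, width, height)
  }
  comps <- split(which(labels > 0L), labels[labels > 0L])
  comps <- comps[vapply(comps, length, integer(1)) >= minPixels]
  if (length(comps) == 0L) return(list())
  peak <- vapply(comps, function(px) max(map[px]), numeric(1))
  comps <- comps[order(-peak)]
  names(comps) <- NULL
  lapply(comps, as.integer)
}

#' Count overexpression spots in one portrait
#'
#' Applies the spot detection rule (per-portrait percentile threshold,
#' 8-connectivity, minimum size) to a single portrait. Because the
#' threshold is a percentile of the portrait itself, the count is
#' invariant to adding a constant.
#'
#' @param portrait Portrait vector (linear pixel order).
#' @param model The `SOMModel` supplying grid dimensions.
#' @param thresholdQuantile,tolerance,minPixels Detection parameters as
#'   in [detectSpots()].
#' @return Integer number of spots.
#' @export
countSampleSpots <- function(portrait, model, thresholdQuantile = 0.82,
                             tolerance = 0.1, minPixels = 4) {
  stopifnot(length(portrait) == nMetagenes(model))
  thr <- stats::quantile(portrait, thresholdQuantile, names = FALSE)
  length(.spotComponents(portrait, model@gridWidth, model@gridHeight,
                         thr, minPixels, tolerance))
}

#' Mean metagene expression over a pixel set
#'
#' @param model A `SOMModel`.
#' @param pixels Integer vector of 1-based linear pixel indices.
#' @return Named per-sample profile.
#' @export
spotExpression <- function(model, pixels) {
  stopifnot(methods::is(model, "SOMModel"),
            all(pixels >= 1L), all(pixels <= nMetagenes(model)))
  colMeans(model@prototypes[pixels, , drop = FALSE])
}

#' Order samples within groups by a spot's expression
#'
#' Helper for spot-profile barplots: samples are ordered within each
#' subtype by increasing expression of a chosen spot.
#'
#' @param spots A `SpotCollection`.
#' @param spot Spot label to sort by.
#' @param groups Named group label per sample.
#' @return Character vector of sample IDs in plotting order.
#' @export
orderSamplesBySpot <- function(spots, spot, groups) {
  stopifnot(spot %in% spots@labels)
  prof <- spots@profiles[spot, ]
  groups <- .alignLabels(groups, colnames(spots@profiles))
  unlist(lapply(split(colnames(spots@profiles), groups), function(s) {
    s[order(prof[s])]
  }), use.names = FALSE)
}

#' One-vs-rest AUC of a spot expression profile
#'
#' AUC is the Mann-Whitney U statistic divided by `n_pos * n_neg` (mid
#' ranks for ties). Values below 0.5 are reported as-is: they mean that
#' under-expression of the spot is the better predictor of the target
#' subtype.
#'
#' @param profile Named per-sample spot expression.
#' @param labels Subtype label per sample (named or aligned).
#' @param target Target subtype (positive class).
#' @return AUC in [0, 1].
#' @export
spotAUC <- function(profile, labels, target) {
  labels <- .alignLabels(labels, names(profile) %||% seq_along(profile))
  if (!target %in% labels) stop("target subtype not present: ", target)
  pos <- labels == target
  if (all(pos)) stop("AUC needs both classes; all samples are ", target)
  .rankAUC(profile, pos)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Ternary coordinates of three spot expression values
#'
#' Negative values are clipped to zero and the triple normalized to sum 1;
#' an all-zero triple maps to the centroid (1/3, 1/3, 1/3).
#'
#' @param x Numeric vector of 3 values or a samples x 3 matrix.
#' @return Vector or matrix of ternary coordinates summing to 1 per row.
#' @export
ternaryCoordinates <- function(x) {
  one <- function(v) {
    v <- pmax(v, 0)
    s <- sum(v)
    if (s == 0) rep(1 / 3, 3) else v / s
  }
  if (is.matrix(x)) {
    stopifnot(ncol(x) == 3L)
    t(apply(x, 1L, one))
  } else {
    stopifnot(length(x) == 3L)
    one(x)
  }
}

#' Signed weighted topological overlap between spots
#'
#' The signed adjacency is the Pearson correlation between spot profiles;
#' the weighted topological overlap augments each pairwise correlation
#' with the shared-neighbor structure:
#' `w_ij = (sum_k a_ik a_kj + a_ij) / (min(k_i, k_j) + 1 - |a_ij|)` with
#' node connectivity `k_i = sum_{k != i} |a_ik|` (the sum excludes i and
#' j). The diagonal is 1. The signed variant preserves anticorrelation
#' between spots.
#'
#' @param profiles Spot x sample expression matrix (e.g.
#'   [spotProfiles()]).
#' @return Symmetric spots x spots wTO matrix.
#' @export
wtoMatrix <- function(profiles) {
  stopifnot(is.matrix(profiles))
  if (nrow(profiles) < 2L) stop("wTO needs at least 2 spots")
  sds <- apply(profiles, 1L, stats::sd)
  if (any(sds == 0)) {
    stop("constant spot profile(s): ",
         paste(rownames(profiles)[sds == 0], collapse = ", "))
  }
  a <- stats::cor(t(profiles))
  a0 <- a
  diag(a0) <- 0
  k <- rowSums(abs(a0))
  num <- a0 %*% a0 + a0
  den <- outer(k, k, pmin) + 1 - abs(a0)
  w <- num / den
  diag(w) <- 1
  dimnames(w) <- dimnames(a)
  w
}

#' Two-group split of a liver-like spot profile
#'
#' Complete-linkage hierarchical clustering of the one-dimensional
#' profile, cut at two clusters; the cluster with the larger mean is
#' labeled "high". Degenerate constant profiles are reported as all-low
#' with a warning.
#'
#' @param profile Named per-sample spot expression.
#' @return List with `labels` (factor "high"/"low" per sample) and
#'   `fractionHigh`.
#' @export
contaminationSplit <- function(profile) {
  if (length(profile) < 2L) stop("need at least 2 samples to split")
  if (stats::sd(profile) == 0) {
    warning("constant profile; reporting all samples as 'low'")
    labs <- factor(rep("low", length(profile)), levels = c("low", "high"))
    names(labs) <- names(profile)
    return(list(labels = labs, fractionHigh = 0))
  }
  hc <- stats::hclust(stats::dist(profile), method = "complete")
  grp <- stats::cutree(hc, k = 2L)
  m1 <- mean(profile[grp == 1L])
  m2 <- mean(profile[grp == 2L])
  high <- if (m1 >= m2) 1L else 2L
  labs <- factor(ifelse(grp == high, "high", "low"), levels = c("low", "high"))
  names(labs) <- names(profile)
  list(labels = labs, fractionHigh = mean(labs == "high"))
}
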