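# Gene-set analysis on the expression matrix and the map: per-sample gene
# set Z scores (GSZ), density maps of set genes over the grid, and
# hypergeometric overrepresentation of sets in spot gene lists.

#' Gene set Z score (GSZ) profile
#'
#' For each sample, the standardized mean expression of the set genes
#' relative to all genes:
#' `GSZ(s) = (mean_set(s) - mean_all(s)) / (sd_all(s) / sqrt(n_set))`,
#' where `n_set` counts the set genes present in the matrix. The score is
#' zero for every sample when the set contains all genes, and reduces to a
#' single gene's within-sample z-score for singleton sets.
#'
#' @param x Centralized expression matrix (genes x samples) or
#'   `SummarizedExperiment`.
#' @param genes Character vector of set member genes; members absent from
#'   the matrix are dropped with a message.
#' @return Named per-sample GSZ vector.
#' @export
gszProfile <- function(x, genes) {
  m <- .getExprs(x)
  present <- intersect(genes, rownames(m))
  if (length(present) == 0L) {
    stop("none of the ", length(genes), " set genes are in the matrix")
  }
  dropped <- length(genes) - length(present)
  if (dropped > 0L) {
    message(dropped, " set gene(s) absent from the matrix were dropped")
  }
  nSet <- length(present)
  meanSet <- colMeans(m[present, , drop = FALSE])
  meanAll <- colMeans(m)
  sdAll <- apply(m, 2L, stats::sd)
  (meanSet - meanAll) / (sdAll / sqrt(nSet))
}

#' GSZ score matrix for a gene-set collection
#'
#' @param x Centralized expression matrix or `SummarizedExperiment`.
#' @param sets Named list of gene sets (e.g. from [readGMT()]).
#' @return Sets x samples score matrix.
#' @export
gszMatrix <- function(x, sets) {
  m <- .getExprs(x)
  out <- t(vapply(sets, function(g) {
    suppressMessages(gszProfile(m, g))
  }, numeric(ncol(m))))
  rownames(out) <- names(sets)
  out
}

#' Density map of a gene set on the grid
#'
#' @param model A [SOMModel-class].
#' @param genes Character vector of set members.
#' @param smoothRadius Optional Gaussian smoothing radius in pixels (0 =
#'   raw counts).
#' @return Numeric map (linear pixel order); without smoothing the pixel
#'   values are the counts of set genes assigned to each metagene and sum
#'   to the number of matchable set genes.
#' @export
setDensityMap <- function(model, genes, smoothRadius = 0) {
  stopifnot(methods::is(model, "SOMModel"))
  present <- intersect(genes, names(model@assignment))
  counts <- tabulate(model@assignment[present], nMetagenes(model))
  if (smoothRadius > 0) {
    cc <- seq_len(model@gridWidth) - 1L
    rr <- seq_len(model@gridHeight) - 1L
    kCol <- exp(-outer(cc, cc, "-")^2 / (2 * smoothRadius^2))
    kRow <- exp(-outer(rr, rr, "-")^2 / (2 * smoothRadius^2))
    counts <- as.vector(.somSmooth(matrix(as.numeric(counts)), kCol, kRow,
                                   model@gridWidth, model@gridHeight))
  }
  as.numeric(counts)
}

#' Overrepresentation of gene sets in a spot gene list
#'
#' One-sided hypergeometric tail probability `P(X >= overlap)` of the
#' observed spot/set overlap in a universe of `universeSize` genes, with
#' fold enrichment `observed / expected` and Benjamini-Hochberg correction
#' across the collection.
#'
#' @param spotGenes Character vector, the spot's gene list.
#' @param sets Named list of gene sets.
#' @param universeSize Number of genes in the universe (e.g. all genes on
#'   the map).
#' @return `data.frame` with one row per set: `set`, `nSet`, `overlap`,
#'   `expected`, `fold`, `p`, `padj`.
#' @export
spotOverrepresentation <- function(spotGenes, sets, universeSize) {
  stopifnot(.isCount(universeSize), length(spotGenes) <= universeSize)
  nSpot <- length(unique(spotGenes))
  res <- lapply(names(sets), function(nm) {
    g <- unique(sets[[nm]])
    if (length(g) > universeSize) {
      stop("set '", nm, "' is larger than the universe")
    }
    ov <- length(intersect(spotGenes, g))
    expected <- nSpot * length(g) / universeSize
    p <- stats::phyper(ov - 1L, length(g), universeSize - length(g), nSpot,
                       lower.tail = FALSE)
    data.frame(set = nm, nSet = length(g), overlap = ov,
               expected = expected,
               fold = if (expected > 0) ov / expected else NA_real_,
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$padj <- stats::p.adjust(out$p, method = "BH")
  out
}
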