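# Principal-tree trajectory over samples in metagene space: PCA to a few
# components, k-means node placement, minimum spanning tree over node
# centroids, nearest-node sample projection, branch-free segment labeling
# and geodesic pseudotime from a root. This is a deliberately simple,
# fully specified principal tree, not a port of any single-cell trajectory
# tool.

#' Fit a principal tree over samples
#'
#' @param metagenes Samples x metagenes matrix (e.g.
#'   `t(prototypes(model))`), or a `SOMModel` whose prototypes are used.
#' @param nComponents Number of principal components (default 10, capped
#'   at `nSamples - 1`).
#' @param nNodes Number of tree nodes (k-means centroids, default 20).
#' @param seed Integer seed (k-means initialization).
#' @return A [TrajectoryTree-class] without segments/pseudotime; pass to
#'   [assignSegmentsPseudotime()].
#' @export
fitPrincipalTree <- function(metagenes, nComponents = 10, nNodes = 20,
                             seed = 1L) {
  if (methods::is(metagenes, "SOMModel")) {
    metagenes <- t(prototypes(metagenes))
  }
  stopifnot(is.matrix(metagenes))
  n <- nrow(metagenes)
  if (nNodes < 2L) stop("need at least 2 nodes")
  if (nNodes > n) stop("more nodes (", nNodes, ") than samples (", n, ")")
  if (nComponents >= n) stop("nComponents must be below the sample count")
  if (is.null(rownames(metagenes))) {
    rownames(metagenes) <- sprintf("sample%03d", seq_len(n))
  }
  keep <- apply(metagenes, 2L, stats::var) > 0
  z <- scale(metagenes[, keep, drop = FALSE], center = TRUE, scale = FALSE)
  k <- min(nComponents, sum(keep))
  pc <- stats::prcomp(z, rank. = k, center = FALSE)
  coords <- pc$x[, seq_len(min(k, ncol(pc$x))), drop = FALSE]

  set.seed(seed)
  km <- stats::kmeans(coords, centers = nNodes, nstart = 5L, iter.max = 100L)
  nodes <- km$centers

  # minimum spanning tree over node centroids (Euclidean weights)
  d <- as.matrix(stats::dist(nodes))
  g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                           weighted = TRUE)
  tree <- igraph::mst(g)
  edges <- igraph::as_edgelist(tree, names = FALSE)
  storage.mode(edges) <- "integer"

  dn <- as.matrix(stats::dist(rbind(nodes, coords)))
  dn <- dn[seq_len(nNodes), nNodes + seq_len(n), drop = FALSE]
  sampleNode <- stats::setNames(apply(dn, 2L, which.min), rownames(metagenes))

  methods::new("TrajectoryTree",
    nodes = nodes, edges = edges,
    sampleNode = as.integer(sampleNode) |> stats::setNames(rownames(metagenes)),
    sampleCoords = coords,
    segment = character(0), nodeSegment = character(0),
    pseudotime = numeric(0), root = 0L,
    segments = data.frame())
}

.treeGraph <- function(tree) {
  g <- igraph::graph_from_edgelist(tree@edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nrow(tree@nodes) - igraph::vcount(g)))
  wts <- sqrt(rowSums((tree@nodes[tree@edges[, 1L], , drop = FALSE] -
                       tree@nodes[tree@edges[, 2L], , drop = FALSE])^2))
  igraph::E(g)$weight <- wts
  g
}

#' Label segments and compute pseudotime
#'
#' Segments are maximal branch-free node paths (edges merged across nodes
#' of degree <= 2, split at branch nodes of degree >= 3), labeled "Seg1",
#' "Seg2", ... in descending order of sample count. Pseudotime is the
#' geodesic distance from the root node along the tree. The root is an
#' explicit node ID, or the leaf whose projected samples have the highest
#' mean expression of a named spot.
#'
#' @param tree A fitted [TrajectoryTree-class].
#' @param root Explicit root node index, or `NULL` to select by spot.
#' @param spots A [SpotCollection-class] (required when selecting the root
#'   by spot).
#' @param rootSpot Spot label whose expression selects the root leaf.
#' @return The tree with segments, pseudotime and root filled in.
#' @export
assignSegmentsPseudotime <- function(tree, root = NULL, spots = NULL,
                                     rootSpot = NULL) {
  stopifnot(methods::is(tree, "TrajectoryTree"))
  g <- .treeGraph(tree)
  nv <- nrow(tree@nodes)
  if (is.null(root)) {
    if (is.null(spots) || is.null(rootSpot)) {
      stop("give an explicit root node or a spot collection + rootSpot")
    }
    if (!rootSpot %in% spotLabels(spots)) {
      stop("unknown spot for root selection: ", rootSpot)
    }
    prof <- spotProfiles(spots)[rootSpot, ]
    leaves <- which(igraph::degree(g) == 1L)
    leafMean <- vapply(leaves, function(v) {
      s <- names(tree@sampleNode)[tree@sampleNode == v]
      if (length(s) == 0L) -Inf else mean(prof[s])
    }, numeric(1))
    root <- leaves[which.max(leafMean)]
  }
  root <- as.integer(root)
  if (root < 1L || root > nv) stop("root node out of range")

  # branch-free segments: union-find over edges joined through degree<=2 nodes
  deg <- igraph::degree(g)
  ne <- nrow(tree@edges)
  parent <- seq_len(ne)
  findRoot <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (v in which(deg <= 2L)) {
    inc <- which(tree@edges[, 1L] == v | tree@edges[, 2L] == v)
    if (length(inc) == 2L) {
      r1 <- findRoot(inc[1L]); r2 <- findRoot(inc[2L])
      if (r1 != r2) parent[r2] <- r1
    }
  }
  edgeSeg <- vapply(seq_len(ne), findRoot, integer(1))
  segIDs <- unique(edgeSeg)

  # node -> segment: non-branch nodes get their unique segment; branch
  # nodes the lowest-numbered adjacent segment (deterministic)
  nodeSegID <- integer(nv)
  for (v in seq_len(nv)) {
    inc <- which(tree@edges[, 1L] == v | tree@edges[, 2L] == v)
    nodeSegID[v] <- min(edgeSeg[inc])
  }
  sampleSegID <- nodeSegID[tree@sampleNode]

  counts <- vapply(segIDs, function(s) sum(sampleSegID == s), integer(1))
  ord <- order(-counts, segIDs)
  segName <- stats::setNames(paste0("Seg", seq_along(segIDs)), segIDs[ord])
  nodeSegment <- unname(segName[as.character(nodeSegID)])
  segment <- stats::setNames(unname(segName[as.character(sampleSegID)]),
                             names(tree@sampleNode))

  pt <- igraph::distances(g, v = root)[1L, ]
  pseudotime <- stats::setNames(pt[tree@sampleNode], names(tree@sampleNode))

  segTab <- data.frame(
    label = unname(segName[as.character(segIDs[ord])]),
    nNodes = vapply(segIDs[ord], function(s) {
      length(unique(as.vector(tree@edges[edgeSeg == s, ])))
    }, integer(1)),
    nSamples = counts[ord],
    stringsAsFactors = FALSE)

  methods::initialize(tree, segment = segment, nodeSegment = nodeSegment,
                      pseudotime = pseudotime, root = root,
                      segments = segTab)
}

#' Overlap coefficient between two sample sets
#'
#' `OC = |A intersect B| / min(|A|, |B|)`.
#'
#' @param setA,setB Nonempty vectors of sample IDs.
#' @return Value in [0, 1].
#' @export
overlapCoefficient <- function(setA, setB) {
  if (length(setA) == 0L || length(setB) == 0L) {
    stop("overlap coefficient needs nonempty sets")
  }
  a <- unique(setA); b <- unique(setB)
  length(intersect(a, b)) / min(length(a), length(b))
}

#' Spot profiles and mean portraits along tree segments
#'
#' Orders the samples of every segment by pseudotime, tabulates spot
#' expression (plus an optional per-sample risk-score column) along each
#' segment, computes per-segment mean portraits, and emits the subtype x
#' segment flow table used for Sankey-style rendering.
#'
#' @param tree A segmented [TrajectoryTree-class].
#' @param model The [SOMModel-class] (for mean portraits).
#' @param spots A [SpotCollection-class].
#' @param subtypes Named subtype label per sample.
#' @param scores Optional named per-sample score (e.g.
#'   [sampleScores()] of a [PrognosticScore-class]).
#' @return List with `profiles` (one ordered `data.frame` per segment),
#'   `meanPortraits` (one map per segment) and `flow` (subtype x segment
#'   contingency table).
#' @export
segmentSpotProfiles <- function(tree, model, spots, subtypes = NULL,
                                scores = NULL) {
  stopifnot(methods::is(tree, "TrajectoryTree"),
            length(tree@segment) > 0L)
  ids <- names(tree@sampleNode)
  prof <- spotProfiles(spots)
  missing <- setdiff(ids, colnames(prof))
  if (length(missing)) {
    stop("samples missing from spot profiles: ",
         paste(missing, collapse = ", "))
  }
  if (!is.null(scores)) {
    missing <- setdiff(ids, names(scores))
    if (length(missing)) {
      stop("samples missing from scores: ", paste(missing, collapse = ", "))
    }
  }
  segs <- unique(tree@segments$label)
  profiles <- lapply(segs, function(sg) {
    s <- ids[tree@segment[ids] == sg]
    s <- s[order(tree@pseudotime[s])]
    out <- data.frame(sample = s, pseudotime = tree@pseudotime[s],
                      t(prof[, s, drop = FALSE]),
                      row.names = NULL, check.names = FALSE)
    if (!is.null(scores)) out$score <- unname(scores[s])
    out
  })
  names(profiles) <- segs
  meanPortraits <- lapply(segs, function(sg) {
    groupMeanPortrait(model, ids[tree@segment[ids] == sg])
  })
  names(meanPortraits) <- segs
  flow <- NULL
  if (!is.null(subtypes)) {
    subtypes <- .alignLabels(subtypes, ids)
    flow <- table(subtype = subtypes, segment = tree@segment[ids])
  }
  list(profiles = profiles, meanPortraits = meanPortraits, flow = flow)
}

#' Export the node tree in Newick format
#'
#' @param tree A [TrajectoryTree-class].
#' @param path Optional path; when given the string is also written there.
#' @return The Newick string, invisibly when writing to a file.
#' @export
treeNewick <- function(tree, path = NULL) {
  g <- .treeGraph(tree)
  root <- if (tree@root > 0L) tree@root else 1L
  build <- function(v, from) {
    nb <- setdiff(as.integer(igraph::neighbors(g, v)), from)
    lab <- paste0("node", v)
    if (length(nb) == 0L) return(lab)
    paste0("(", paste(vapply(nb, build, character(1), from = v),
                      collapse = ","), ")", lab)
  }
  nwk <- paste0(build(root, integer(0)), ";")
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}
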