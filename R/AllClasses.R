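#' SOMModel: a trained metagene grid
#'
#' Holds the prototype ("metagene") profiles of a trained self-organizing
#' map together with the gene-to-metagene assignment. Prototype rows are in
#' row-major linear pixel order (`index = row * width + col`, 0-based
#' coordinates, origin top-left); columns are samples.
#'
#' @slot gridWidth,gridHeight Grid dimensions in pixels.
#' @slot prototypes Numeric matrix, (width * height) metagenes x samples.
#' @slot assignment Named integer vector mapping each gene to the linear
#'   index of its best-matching unit.
#' @slot epochs Number of batch training sweeps.
#' @slot radiusSchedule Neighborhood radius used at each epoch.
#' @slot seed Integer seed used for training.
#' @slot qe Quantization-error trace, one value per epoch.
#' @export
setClass("SOMModel",
  representation(
    gridWidth = "integer",
    gridHeight = "integer",
    prototypes = "matrix",
    assignment = "integer",
    epochs = "integer",
    radiusSchedule = "numeric",
    seed = "integer",
    qe = "numeric"
  )
)

setValidity("SOMModel", function(object) {
  msg <- NULL
  u <- object@gridWidth * object@gridHeight
  if (nrow(object@prototypes) != u) {
    msg <- c(msg, "prototype row count must equal gridWidth * gridHeight")
  }
  if (is.null(colnames(object@prototypes))) {
    msg <- c(msg, "prototypes must carry sample IDs as column names")
  }
  if (is.null(names(object@assignment))) {
    msg <- c(msg, "assignment must be named by gene ID")
  }
  if (length(object@assignment) &&
      (min(object@assignment) < 1L || max(object@assignment) > u)) {
    msg <- c(msg, "assignment indices outside the grid")
  }
  if (anyDuplicated(names(object@assignment))) {
    msg <- c(msg, "duplicate gene IDs in assignment")
  }
  if (is.null(msg)) TRUE else msg
})

#' SpotCollection: overexpression spot modules on the map
#'
#' Connected pixel regions of a summary map above a detection threshold,
#' each with the genes assigned to its pixels and a per-sample expression
#' profile (mean metagene expression over the pixel set). Spots are labeled
#' "A", "B", ... in descending order of peak map value.
#'
#' @slot labels Spot labels.
#' @slot pixels List of integer vectors (1-based linear pixel indices).
#' @slot genes List of character vectors of member genes.
#' @slot profiles Numeric matrix, spots x samples.
#' @slot map The summary map the spots were detected on.
#' @slot gridWidth,gridHeight Grid dimensions.
#' @slot threshold Numeric detection threshold on the map scale.
#' @slot minPixels Minimum component size retained.
#' @export
setClass("SpotCollection",
  representation(
    labels = "character",
    pixels = "list",
    genes = "list",
    profiles = "matrix",
    map = "numeric",
    gridWidth = "integer",
    gridHeight = "integer",
    threshold = "numeric",
    minPixels = "integer"
  )
)

setValidity("SpotCollection", function(object) {
  msg <- NULL
  n <- length(object@labels)
  if (length(object@pixels) != n || length(object@genes) != n) {
    msg <- c(msg, "labels, pixels and genes must have equal length")
  }
  if (n && nrow(object@profiles) != n) {
    msg <- c(msg, "profile rows must match the number of spots")
  }
  if (anyDuplicated(object@labels)) msg <- c(msg, "spot labels must be unique")
  if (is.null(msg)) TRUE else msg
})

#' HRMap: per-metagene hazard ratios
#'
#' Per-pixel hazard ratios from univariate proportional-hazards fits of a
#' high-expression group indicator against overall survival. Pixels whose
#' high-expression arm is smaller than the minimum group size, or whose fit
#' did not converge, are masked (HR stored as NA).
#'
#' @slot hr Numeric vector of hazard ratios in linear pixel order (NA where
#'   masked).
#' @slot nHigh Integer vector, size of the high-expression group per pixel.
#' @slot masked Logical vector of masked pixels.
#' @slot mode Threshold mode used, "gt-mean" or "gt-1sd".
#' @slot minGroup Minimum group size per arm.
#' @slot gridWidth,gridHeight Grid dimensions.
#' @export
setClass("HRMap",
  representation(
    hr = "numeric",
    nHigh = "integer",
    masked = "logical",
    mode = "character",
    minGroup = "integer",
    gridWidth = "integer",
    gridHeight = "integer"
  )
)

setValidity("HRMap", function(object) {
  msg <- NULL
  u <- object@gridWidth * object@gridHeight
  if (length(object@hr) != u || length(object@masked) != u) {
    msg <- c(msg, "hr and masked must cover every pixel")
  }
  ok <- !object@masked
  if (any(ok) && any(!is.finite(object@hr[ok]) | object@hr[ok] <= 0)) {
    msg <- c(msg, "unmasked hazard ratios must be positive and finite")
  }
  if (any(object@masked & !is.na(object@hr))) {
    msg <- c(msg, "masked pixels must have NA hazard ratios")
  }
  if (is.null(msg)) TRUE else msg
})

#' PrognosticScore: extreme-HR metagenes and the per-sample risk score
#'
#' The maximum- and minimum-HR pixels of an HR map, their gene lists, and
#' the per-sample score defined as the difference of mean expression over
#' the two lists (higher score = worse predicted prognosis).
#'
#' @slot maxPixel,minPixel Linear pixel indices of the HR extremes.
#' @slot maxGenes,minGenes Gene lists of the extreme metagenes (padded from
#'   the pixel neighborhood up to a minimum count).
#' @slot maxHR,minHR Hazard ratios at the extreme pixels.
#' @slot scores Named per-sample score vector.
#' @export
setClass("PrognosticScore",
  representation(
    maxPixel = "integer",
    minPixel = "integer",
    maxGenes = "character",
    minGenes = "character",
    maxHR = "numeric",
    minHR = "numeric",
    scores = "numeric"
  )
)

setValidity("PrognosticScore", function(object) {
  msg <- NULL
  if (length(object@maxGenes) == 0L || length(object@minGenes) == 0L) {
    msg <- c(msg, "extreme metagenes must carry nonempty gene lists")
  }
  if (length(object@maxHR) && length(object@minHR) &&
      object@maxHR < object@minHR) {
    msg <- c(msg, "maxHR must be >= minHR")
  }
  if (length(object@scores) && any(!is.finite(object@scores))) {
    msg <- c(msg, "scores must be finite for every sample")
  }
  if (is.null(msg)) TRUE else msg
})

#' TrajectoryTree: principal tree over samples in metagene space
#'
#' Nodes placed in a reduced (principal-component) space, connected by a
#' minimum spanning tree; samples project to their nearest node. Segments
#' are maximal branch-free node paths; pseudotime is the geodesic distance
#' from the root node along the tree.
#'
#' @slot nodes Numeric matrix of node coordinates (nodes x components).
#' @slot edges Two-column integer matrix of tree edges.
#' @slot sampleNode Named integer vector, nearest node per sample.
#' @slot sampleCoords Sample coordinates in the reduced space.
#' @slot segment Named character vector, segment label per sample.
#' @slot nodeSegment Character vector, segment label per node.
#' @slot pseudotime Named numeric vector, geodesic distance from the root.
#' @slot root Root node index (0 = unset).
#' @slot segments Summary table (label, nodes, sample count).
#' @export
setClass("TrajectoryTree",
  representation(
    nodes = "matrix",
    edges = "matrix",
    sampleNode = "integer",
    sampleCoords = "matrix",
    segment = "character",
    nodeSegment = "character",
    pseudotime = "numeric",
    root = "integer",
    segments = "data.frame"
  )
)

setValidity("TrajectoryTree", function(object) {
  msg <- NULL
  nv <- nrow(object@nodes)
  if (nrow(object@edges) != nv - 1L) {
    msg <- c(msg, "a tree on V nodes must have V - 1 edges")
  }
  g <- igraph::graph_from_edgelist(object@edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nv - igraph::vcount(g)))
  if (!igraph::is_connected(g)) msg <- c(msg, "tree must be connected")
  if (length(object@pseudotime) && any(object@pseudotime < 0)) {
    msg <- c(msg, "pseudotime must be >= 0")
  }
  if (is.null(msg)) TRUE else msg
})
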