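#' @name somscape-accessors
#' @title Accessors for somscape classes
#' @param object A somscape object.
#' @description Accessor generics for the central classes: grid geometry,
#'   prototype matrix, gene assignment, spot contents, hazard-ratio values
#'   and per-sample scores.
NULL

#' @rdname somscape-accessors
#' @export
setGeneric("gridSize", function(object) standardGeneric("gridSize"))

#' @rdname somscape-accessors
#' @export
setGeneric("prototypes", function(object) standardGeneric("prototypes"))

#' @rdname somscape-accessors
#' @export
setGeneric("geneAssignment", function(object) standardGeneric("geneAssignment"))

#' @rdname somscape-accessors
#' @export
setGeneric("sampleIDs", function(object) standardGeneric("sampleIDs"))

#' @rdname somscape-accessors
#' @export
setGeneric("spotLabels", function(object) standardGeneric("spotLabels"))

#' @rdname somscape-accessors
#' @export
setGeneric("spotPixels", function(object) standardGeneric("spotPixels"))

#' @rdname somscape-accessors
#' @export
setGeneric("spotGenes", function(object) standardGeneric("spotGenes"))

#' @rdname somscape-accessors
#' @export
setGeneric("spotProfiles", function(object) standardGeneric("spotProfiles"))

#' @rdname somscape-accessors
#' @export
setGeneric("hrValues", function(object) standardGeneric("hrValues"))

#' @rdname somscape-accessors
#' @export
setGeneric("maskedPixels", function(object) standardGeneric("maskedPixels"))

#' @rdname somscape-accessors
#' @export
setGeneric("sampleScores", function(object) standardGeneric("sampleScores"))

#' @rdname somscape-accessors
#' @export
setGeneric("pseudotimes", function(object) standardGeneric("pseudotimes"))

#' @rdname somscape-accessors
#' @export
setGeneric("sampleSegments", function(object) standardGeneric("sampleSegments"))

#' @rdname somscape-accessors
setMethod("gridSize", "SOMModel", function(object) {
  c(width = object@gridWidth, height = object@gridHeight)
})

#' @rdname somscape-accessors
setMethod("prototypes", "SOMModel", function(object) object@prototypes)

#' @rdname somscape-accessors
setMethod("geneAssignment", "SOMModel", function(object) object@assignment)

#' @rdname somscape-accessors
setMethod("sampleIDs", "SOMModel", function(object) colnames(object@prototypes))

#' Number of metagenes of a trained map
#' @param object A `SOMModel`.
#' @return Integer, width * height.
#' @export
nMetagenes <- function(object) {
  stopifnot(methods::is(object, "SOMModel"))
  object@gridWidth * object@gridHeight
}

#' @rdname somscape-accessors
setMethod("spotLabels", "SpotCollection", function(object) object@labels)

#' @rdname somscape-accessors
setMethod("spotPixels", "SpotCollection", function(object) {
  stats::setNames(object@pixels, object@labels)
})

#' @rdname somscape-accessors
setMethod("spotGenes", "SpotCollection", function(object) {
  stats::setNames(object@genes, object@labels)
})

#' @rdname somscape-accessors
setMethod("spotProfiles", "SpotCollection", function(object) object@profiles)

#' @rdname somscape-accessors
setMethod("hrValues", "HRMap", function(object) object@hr)

#' @rdname somscape-accessors
setMethod("maskedPixels", "HRMap", function(object) object@masked)

#' @rdname somscape-accessors
setMethod("sampleScores", "PrognosticScore", function(object) object@scores)

#' @rdname somscape-accessors
setMethod("pseudotimes", "TrajectoryTree", function(object) object@pseudotime)

#' @rdname somscape-accessors
setMethod("sampleSegments", "TrajectoryTree", function(object) object@segment)

setMethod("show", "SOMModel", function(object) {
  cat("SOMModel:", object@gridWidth, "x", object@gridHeight, "grid,",
      nrow(object@prototypes), "metagenes\n")
  cat("  genes:", length(object@assignment),
      " samples:", ncol(object@prototypes), "\n")
  cat("  epochs:", object@epochs,
      " final quantization error:",
      signif(utils::tail(object@qe, 1L), 4), "\n")
})

setMethod("show", "SpotCollection", function(object) {
  cat("SpotCollection:", length(object@labels), "spot(s) on a",
      object@gridWidth, "x", object@gridHeight, "grid\n")
  if (length(object@labels)) {
    sizes <- vapply(object@pixels, length, integer(1))
    ng <- vapply(object@genes, length, integer(1))
    cat("  ", paste0(object@labels, " (", sizes, " px, ", ng, " genes)",
                     collapse = ", "), "\n", sep = "")
  }
})

setMethod("show", "HRMap", function(object) {
  ok <- !object@masked
  cat("HRMap (", object@mode, "): ", sum(ok), "/", length(object@hr),
      " pixels unmasked\n", sep = "")
  if (any(ok)) {
    cat("  HR range:", signif(min(object@hr[ok]), 3), "-",
        signif(max(object@hr[ok]), 3), "\n")
  }
})

setMethod("show", "PrognosticScore", function(object) {
  cat("PrognosticScore: maxHR pixel", object@maxPixel,
      sprintf("(HR %.3g, %d genes),", object@maxHR, length(object@maxGenes)),
      "minHR pixel", object@minPixel,
      sprintf("(HR %.3g, %d genes)\n", object@minHR, length(object@minGenes)))
  cat("  scores for", length(object@scores), "samples\n")
})

setMethod("show", "TrajectoryTree", function(object) {
  cat("TrajectoryTree:", nrow(object@nodes), "nodes,",
      nrow(object@edges), "edges,", length(object@sampleNode), "samples\n")
  if (nrow(object@segments)) {
    cat("  segments:", paste0(object@segments$label, " (n=",
        object@segments$nSamples, ")", collapse = ", "), "\n")
  }
})
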