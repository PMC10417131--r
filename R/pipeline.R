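# End-to-end orchestration: a validated flat configuration, staged
# execution (preprocess -> train -> spots -> genesets -> trajectory ->
# prognosis), TSV/GMT outputs and a JSON run manifest. Reruns with the
# same configuration and seed reproduce all tabular outputs
# bit-identically.

.configDefaults <- function() {
  list(
    expression = NULL, annotation = NULL, survival = NULL, gmt = NULL,
    synthetic = FALSE, nSamples = 120L, nGenes = 6000L,
    log10 = FALSE, qnorm = FALSE, log10Offset = 0,
    gridWidth = 50L, gridHeight = 50L, epochs = 30L,
    spotQuantile = 0.82, spotTolerance = 0.1, spotMinPixels = 4L,
    summary = "group",
    nComponents = 10L, nNodes = 20L, rootSpot = NULL,
    hrMode = "gt-mean", minGroup = 5L, percentile = 25,
    skip = character(0),
    seed = 1L, outDir = "somscape-run"
  )
}

#' Build and validate a pipeline configuration
#'
#' @param ... Key = value overrides of the defaults: input paths
#'   (`expression`, `annotation`, `survival`, `gmt`) or `synthetic =
#'   TRUE`; preprocessing flags (`log10`, `qnorm`, `log10Offset`); SOM
#'   parameters (`gridWidth`, `gridHeight`, `epochs`); spot detection
#'   (`spotQuantile`, `spotMinPixels`, `summary` = "group" or
#'   "personalized"); trajectory (`nComponents`, `nNodes`, `rootSpot`);
#'   prognostics (`hrMode`, `minGroup`, `percentile`); `skip` (stage
#'   names among "genesets", "trajectory", "prognosis"); `seed`;
#'   `outDir`. Unknown keys are rejected.
#' @return Validated config list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(...) {
  cfg <- .configDefaults()
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  }
  cfg[names(over)] <- over
  if (!cfg$synthetic && is.null(cfg$expression)) {
    stop("either synthetic = TRUE or an expression path is required")
  }
  bad <- setdiff(cfg$skip, c("genesets", "trajectory", "prognosis"))
  if (length(bad)) stop("cannot skip unknown stage(s): ",
                        paste(bad, collapse = ", "))
  if (!cfg$summary %in% c("group", "personalized")) {
    stop("summary must be 'group' or 'personalized'")
  }
  if (!cfg$synthetic && !"prognosis" %in% cfg$skip &&
      is.null(cfg$survival)) {
    stop("prognosis stage requested but no survival table configured; ",
         "supply `survival` or add \"prognosis\" to `skip`")
  }
  structure(cfg, class = "PipelineConfig")
}

#' Run the full portrayal pipeline
#'
#' Stages run in order: preprocess, train, spots, genesets, trajectory,
#' prognosis. Each stage's outputs land under `outDir` and are recorded
#' in `manifest.json` together with the package version, the seed and the
#' resolved configuration.
#'
#' @param config A `PipelineConfig` from [pipelineConfig()].
#' @return Invisibly, a list with the in-memory results (`model`,
#'   `spots`, `tree`, `hrmap`, `score`, ...) and the manifest.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "somscape",
                   version = as.character(utils::packageVersion("somscape")),
                   seed = config$seed,
                   config = unclass(config)[!vapply(config, is.null, TRUE)],
                   stages = list())
  outputs <- character(0)
  stage <- "input"
  res <- list()
  tryCatch({
    if (config$synthetic) {
      design <- defaultCohortDesign(nSamples = config$nSamples,
                                    seed = config$seed,
                                    nGenes = config$nGenes)
      cohort <- generateCohort(design)
      surv <- attachSurvival(cohort, seed = config$seed)
      x <- SummarizedExperiment::assay(cohort)
      ann <- as.data.frame(SummarizedExperiment::colData(cohort))
      sets <- NULL
    } else {
      x <- readExpressionMatrix(config$expression)
      ann <- if (!is.null(config$annotation)) {
        readSampleAnnotation(config$annotation)
      } else NULL
      surv <- if (!is.null(config$survival)) {
        readSurvivalTable(config$survival)
      } else NULL
      sets <- if (!is.null(config$gmt)) readGMT(config$gmt) else NULL
    }

    stage <- "preprocess"
    x <- preprocessExpression(x, log10 = config$log10, qnorm = config$qnorm,
                              offset = config$log10Offset)
    manifest$stages$preprocess <- list(nGenes = nrow(x), nSamples = ncol(x))

    stage <- "train"
    model <- trainSOM(x, gridWidth = config$gridWidth,
                      gridHeight = config$gridHeight,
                      epochs = config$epochs, seed = config$seed)
    f <- file.path(config$outDir, "metagenes.tsv")
    writeExpressionMatrix(
      `rownames<-`(prototypes(model),
                   sprintf("metagene%04d", seq_len(nMetagenes(model)))), f)
    outputs <- c(outputs, f)
    f <- file.path(config$outDir, "gene_assignment.tsv")
    utils::write.table(
      data.frame(gene = names(geneAssignment(model)),
                 metagene = unname(geneAssignment(model))),
      f, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs <- c(outputs, f)
    manifest$stages$train <- list(grid = unname(gridSize(model)),
                                  epochs = config$epochs,
                                  finalQE = utils::tail(model@qe, 1L))

    stage <- "spots"
    subtype <- if (!is.null(ann)) {
      stats::setNames(ann$subtype, ann$sample)
    } else NULL
    maps <- supportingMaps(model, groups = subtype)
    summaryMap <- if (config$summary == "group" && !is.null(maps$groupSummary)) {
      maps$groupSummary
    } else maps$personalizedSummary
    spots <- detectSpots(model, summaryMap,
                         thresholdQuantile = config$spotQuantile,
                         tolerance = config$spotTolerance,
                         minPixels = config$spotMinPixels)
    f <- file.path(config$outDir, "spots.gmt")
    if (length(spotLabels(spots))) {
      writeGMT(spotGenes(spots), f,
               descriptions = paste0("spot ", spotLabels(spots)))
      outputs <- c(outputs, f)
      f <- file.path(config$outDir, "spot_profiles.tsv")
      utils::write.table(
        data.frame(spot = spotLabels(spots), spotProfiles(spots),
                   check.names = FALSE),
        f, sep = "\t", quote = FALSE, row.names = FALSE)
      outputs <- c(outputs, f)
    }
    manifest$stages$spots <- list(n = length(spotLabels(spots)),
                                  threshold = spots@threshold)

    if (!"genesets" %in% config$skip && !is.null(sets)) {
      stage <- "genesets"
      gsz <- gszMatrix(x, sets)
      f <- file.path(config$outDir, "gsz.tsv")
      utils::write.table(data.frame(set = rownames(gsz), gsz,
                                    check.names = FALSE),
                         f, sep = "\t", quote = FALSE, row.names = FALSE)
      outputs <- c(outputs, f)
      manifest$stages$genesets <- list(nSets = nrow(gsz))
      res$gsz <- gsz
    }

    tree <- NULL
    if (!"trajectory" %in% config$skip) {
      stage <- "trajectory"
      tree <- fitPrincipalTree(t(prototypes(model)),
                               nComponents = config$nComponents,
                               nNodes = config$nNodes, seed = config$seed)
      rootSpot <- config$rootSpot
      if (is.null(rootSpot) && length(spotLabels(spots))) {
        rootSpot <- spotLabels(spots)[1L]
      }
      tree <- assignSegmentsPseudotime(tree, spots = spots,
                                       rootSpot = rootSpot)
      f <- file.path(config$outDir, "trajectory.tsv")
      utils::write.table(
        data.frame(sample = names(tree@sampleNode),
                   node = unname(tree@sampleNode),
                   segment = unname(tree@segment),
                   pseudotime = unname(tree@pseudotime)),
        f, sep = "\t", quote = FALSE, row.names = FALSE)
      outputs <- c(outputs, f)
      f <- file.path(config$outDir, "tree.nwk")
      treeNewick(tree, f)
      outputs <- c(outputs, f)
      manifest$stages$trajectory <- list(
        nSegments = nrow(tree@segments), root = tree@root)
    } else {
      manifest$stages$trajectory <- list(skipped = TRUE)
    }

    score <- NULL
    hrmap <- NULL
    if (!"prognosis" %in% config$skip && !is.null(surv)) {
      stage <- "prognosis"
      hrmap <- hrMap(model, surv, mode = config$hrMode,
                     minGroup = config$minGroup)
      skel <- extremeMetagenes(hrmap, model)
      score <- deltaHRScore(x, skel)
      split <- splitRiskGroups(sampleScores(score), surv,
                               percentile = config$percentile)
      f <- file.path(config$outDir, "hr_map.tsv")
      utils::write.table(
        data.frame(pixel = seq_along(hrValues(hrmap)),
                   hr = hrValues(hrmap), nHigh = hrmap@nHigh,
                   masked = maskedPixels(hrmap)),
        f, sep = "\t", quote = FALSE, row.names = FALSE)
      outputs <- c(outputs, f)
      f <- file.path(config$outDir, "delta_hr_scores.tsv")
      sc <- sampleScores(score)
      utils::write.table(
        data.frame(sample = names(sc), score = unname(sc),
                   rank = rank(sc, ties.method = "first"),
                   group = as.character(split$groups[names(sc)])),
        f, sep = "\t", quote = FALSE, row.names = FALSE)
      outputs <- c(outputs, f)
      manifest$stages$prognosis <- list(
        maxPixel = score@maxPixel, minPixel = score@minPixel,
        logrankP = split$p)
      res$split <- split
    } else {
      manifest$stages$prognosis <- list(skipped = TRUE)
    }

    manifest$outputs <- outputs
    jsonlite::write_json(manifest,
                         file.path(config$outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    res <- c(list(model = model, spots = spots, tree = tree,
                  hrmap = hrmap, score = score, manifest = manifest), res)
    invisible(res)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
}
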