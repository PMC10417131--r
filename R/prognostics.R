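# Prognostic maps and the derived risk score: per-metagene hazard ratios
# from univariate Cox fits of a high-expression indicator, extreme-HR
# metagene extraction with neighborhood gene padding, the per-sample
# score (mean expression over maxHR genes minus mean over minHR genes),
# percentile risk-group splits with Kaplan-Meier curves and a log-rank
# test, and per-patient heterogeneity of the score.

.alignSurvival <- function(survival, ids) {
  need <- c("sample", "os_time", "event")
  if (!all(need %in% colnames(survival))) {
    stop("survival table must contain columns: ", paste(need, collapse = ", "))
  }
  missing <- setdiff(ids, survival$sample)
  if (length(missing)) {
    stop("survival data missing for samples: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  }
  survival[match(ids, survival$sample), , drop = FALSE]
}

#' Per-metagene hazard-ratio map
#'
#' For every pixel, samples are split into a high-expression group
#' (centralized metagene expression > 0, or > +1 within-pixel SD) and the
#' rest, and the hazard ratio is `exp(beta)` from a univariate Cox
#' proportional-hazards fit of the group indicator against overall
#' survival (Efron tie handling). Pixels with fewer than `minGroup`
#' samples in either arm, or with a non-convergent fit, are masked.
#'
#' @param model A [SOMModel-class] trained on centralized data.
#' @param survival Survival table with columns `sample`, `os_time`,
#'   `event` covering all model samples.
#' @param mode `"gt-mean"` (expression > 0) or `"gt-1sd"` (> 1 pixel SD).
#' @param minGroup Minimum samples per arm (default 5).
#' @return An [HRMap-class].
#' @export
hrMap <- function(model, survival, mode = c("gt-mean", "gt-1sd"),
                  minGroup = 5) {
  stopifnot(methods::is(model, "SOMModel"), minGroup >= 2)
  mode <- match.arg(mode)
  ids <- sampleIDs(model)
  surv <- .alignSurvival(survival, ids)
  if (all(surv$event == 0L)) stop("all samples are censored; cannot fit")
  y <- survival::Surv(surv$os_time, surv$event)
  ctrl <- survival::coxph.control()
  w <- model@prototypes
  nU <- nrow(w)
  hr <- rep(NA_real_, nU)
  nHigh <- integer(nU)
  masked <- rep(TRUE, nU)
  for (u in seq_len(nU)) {
    v <- w[u, ]
    thr <- if (mode == "gt-mean") 0 else stats::sd(v)
    grp <- as.numeric(v > thr)
    nHigh[u] <- as.integer(sum(grp))
    if (min(nHigh[u], length(grp) - nHigh[u]) < minGroup) next
    fit <- tryCatch(
      suppressWarnings(survival::coxph.fit(
        matrix(grp), y, strata = NULL, offset = NULL, init = 0,
        control = ctrl, weights = NULL, method = "efron",
        rownames = NULL)),
      error = function(e) NULL)
    if (is.null(fit)) next
    beta <- unname(fit$coefficients[1L])
    if (!is.finite(beta) || abs(beta) > 10) next
    hr[u] <- exp(beta)
    masked[u] <- FALSE
  }
  methods::new("HRMap", hr = hr, nHigh = nHigh, masked = masked,
               mode = mode, minGroup = as.integer(minGroup),
               gridWidth = model@gridWidth, gridHeight = model@gridHeight)
}

# Gaussian smoothing of a map with NA (masked) pixels via normalized
# convolution; NA pixels stay NA.
.smoothMaskedMap <- function(v, width, height, sigma) {
  cc <- seq_len(width) - 1L
  rr <- seq_len(height) - 1L
  kCol <- exp(-outer(cc, cc, "-")^2 / (2 * sigma^2))
  kRow <- exp(-outer(rr, rr, "-")^2 / (2 * sigma^2))
  m <- matrix(v, width, height)
  filled <- !is.na(m)
  m[!filled] <- 0
  num <- kCol %*% m %*% kRow
  den <- kCol %*% (filled + 0) %*% kRow
  out <- num / den
  out[!filled] <- NA
  as.vector(out)
}

# genes ordered by Chebyshev ring distance from a pixel, then by linear
# pixel index, then by assignment order within a pixel
.neighborhoodGenes <- function(model, pixel, maxRadius = NULL) {
  coords <- .gridCoords(model@gridWidth, model@gridHeight)
  p <- coords[pixel, ]
  ring <- pmax(abs(coords[, "col"] - p[["col"]]),
               abs(coords[, "row"] - p[["row"]]))
  if (is.null(maxRadius)) maxRadius <- max(ring)
  ord <- order(ring, seq_along(ring))
  ord <- ord[ring[ord] <= maxRadius]
  pixRank <- match(model@assignment, ord)
  genes <- names(model@assignment)[!is.na(pixRank)]
  genes[order(pixRank[!is.na(pixRank)])]
}

#' Extreme-HR metagenes and their gene lists
#'
#' Finds the unmasked pixels with the maximum and minimum hazard ratio
#' (ties resolved to the lower linear pixel index) and collects the genes
#' assigned to each. Because neighboring metagenes carry near-identical
#' profiles, per-pixel hazard-ratio estimates are spatially coherent
#' while their noise is not; by default the log-HR map is therefore
#' smoothed with a small Gaussian kernel (`smoothRadius` pixels, masked
#' pixels excluded by normalized convolution) before taking the extremes,
#' so that blob-level extremes win over isolated noisy pixels.
#' `smoothRadius = 0` selects raw per-pixel extremes. If an extreme pixel
#' hosts fewer than `minGenes` genes, its list is padded with genes from
#' growing square neighborhoods (8-neighbor rings), stopping exactly at
#' `minGenes`.
#'
#' @param map An [HRMap-class].
#' @param model The [SOMModel-class] the map was computed on.
#' @param minGenes Minimum genes per extreme metagene (default 20).
#' @param smoothRadius Gaussian radius (pixels) for log-HR smoothing
#'   before extreme selection (default 1.5; 0 = no smoothing).
#' @return A [PrognosticScore-class] skeleton (scores empty; fill with
#'   [deltaHRScore()]). The recorded `maxHR`/`minHR` are the raw
#'   (unsmoothed) hazard ratios at the selected pixels.
#' @export
extremeMetagenes <- function(map, model, minGenes = 20, smoothRadius = 1.5) {
  stopifnot(methods::is(map, "HRMap"), methods::is(model, "SOMModel"))
  ok <- which(!map@masked)
  if (length(ok) == 0L) stop("fully masked HR map")
  crit <- log(map@hr)
  if (smoothRadius > 0) {
    crit <- .smoothMaskedMap(crit, map@gridWidth, map@gridHeight,
                             smoothRadius)
  }
  maxPixel <- ok[which.max(crit[ok])]
  minPixel <- ok[which.min(crit[ok])]
  pad <- function(pixel) {
    genes <- .neighborhoodGenes(model, pixel, maxRadius = 0L)
    if (length(genes) < minGenes) {
      all <- .neighborhoodGenes(model, pixel)
      genes <- all[seq_len(min(minGenes, length(all)))]
    }
    genes
  }
  methods::new("PrognosticScore",
    maxPixel = as.integer(maxPixel), minPixel = as.integer(minPixel),
    maxGenes = pad(maxPixel), minGenes = pad(minPixel),
    maxHR = map@hr[maxPixel], minHR = map@hr[minPixel],
    scores = numeric(0))
}

#' Spot-based variant of the score skeleton
#'
#' Substitutes two spot gene lists for the extreme-pixel gene lists, for
#' scoring along a spot axis instead of single extreme metagenes.
#'
#' @param spots A [SpotCollection-class].
#' @param highSpot,lowSpot Spot labels for the high-risk and low-risk gene
#'   lists.
#' @param map Optional [HRMap-class] to record spot-level HR values (mean
#'   over spot pixels).
#' @return A [PrognosticScore-class] skeleton.
#' @export
spotScoreSkeleton <- function(spots, highSpot, lowSpot, map = NULL) {
  stopifnot(all(c(highSpot, lowSpot) %in% spotLabels(spots)))
  px <- spotPixels(spots)
  hrAt <- function(pixels) {
    if (is.null(map)) return(NA_real_)
    mean(map@hr[pixels], na.rm = TRUE)
  }
  hi <- hrAt(px[[highSpot]])
  lo <- hrAt(px[[lowSpot]])
  methods::new("PrognosticScore",
    maxPixel = px[[highSpot]][1L], minPixel = px[[lowSpot]][1L],
    maxGenes = spotGenes(spots)[[highSpot]],
    minGenes = spotGenes(spots)[[lowSpot]],
    maxHR = if (is.na(hi)) 1 else hi, minHR = if (is.na(lo)) 1 else lo,
    scores = numeric(0))
}

#' Per-sample risk score from extreme-HR gene lists
#'
#' `score(s) = mean expression over maxHR genes - mean over minHR genes`
#' on the centralized matrix; swapping the two lists negates the score
#' exactly.
#'
#' @param x Centralized expression matrix or `SummarizedExperiment`.
#' @param skeleton A [PrognosticScore-class] skeleton.
#' @return The skeleton with `scores` filled (named by sample, ascending
#'   rank order available via `sort()`).
#' @export
deltaHRScore <- function(x, skeleton) {
  stopifnot(methods::is(skeleton, "PrognosticScore"))
  m <- .getExprs(x)
  for (side in list(skeleton@maxGenes, skeleton@minGenes)) {
    if (length(side) == 0L) stop("empty extreme gene list")
    missing <- setdiff(side, rownames(m))
    if (length(missing)) {
      stop("score genes absent from the matrix: ",
           paste(utils::head(missing, 5L), collapse = ", "))
    }
  }
  hi <- colMeans(m[skeleton@maxGenes, , drop = FALSE])
  lo <- colMeans(m[skeleton@minGenes, , drop = FALSE])
  methods::initialize(skeleton, scores = hi - lo)
}

#' Split samples into high- and low-risk groups
#'
#' High risk = top `percentile`% of samples by score, low risk = bottom
#' `percentile`% (ties broken by sample ID order). Returns the group
#' labels, Kaplan-Meier estimates per group and the two-group log-rank
#' test.
#'
#' @param scores Named per-sample score (higher = worse prognosis).
#' @param survival Survival table covering the scored samples.
#' @param percentile Percent per tail, in (0, 50].
#' @return List with `groups` (named factor `high`/`low`, NA in the
#'   middle), `km` (a `survfit` object over the two groups), `chisq` and
#'   `p` of the log-rank test.
#' @export
splitRiskGroups <- function(scores, survival, percentile = 25) {
  if (percentile <= 0 || percentile > 50) {
    stop("percentile must be in (0, 50]")
  }
  ids <- names(scores)
  if (is.null(ids)) stop("scores must be named by sample")
  surv <- .alignSurvival(survival, ids)
  n <- length(scores)
  k <- floor(n * percentile / 100)
  if (k < 2L) stop("risk groups would have fewer than 2 samples")
  ord <- order(-scores, ids)
  groups <- factor(rep(NA_character_, n), levels = c("low", "high"))
  names(groups) <- ids
  groups[ids[ord[seq_len(k)]]] <- "high"
  groups[ids[rev(ord)[seq_len(k)]]] <- "low"
  sel <- !is.na(groups)
  y <- survival::Surv(surv$os_time[sel], surv$event[sel])
  g <- droplevels(groups[sel])
  km <- survival::survfit(y ~ g)
  lr <- survival::survdiff(y ~ g)
  p <- stats::pchisq(lr$chisq, df = 1L, lower.tail = FALSE)
  list(groups = groups, km = km, chisq = unname(lr$chisq), p = p)
}

#' Intra-patient heterogeneity of a per-sample score
#'
#' Per patient: mean and sample SD of the lesion scores (SD is NA for
#' single-lesion patients), ranked by ascending mean; plus a cohort
#' summary comparing the spread of patient means with the mean
#' within-patient SD.
#'
#' @param scores Named per-sample score.
#' @param patients Patient ID per sample (named or aligned with
#'   `scores`).
#' @return List with `perPatient` (`data.frame`: patient, nLesions, mean,
#'   sd, rank) and `summary` (`rangeOfMeans`, `meanWithinSD` over
#'   multi-lesion patients).
#' @export
patientHeterogeneity <- function(scores, patients) {
  patients <- .alignLabels(patients, names(scores) %||% seq_along(scores))
  sp <- split(unname(scores), patients)
  perPatient <- data.frame(
    patient = names(sp),
    nLesions = vapply(sp, length, integer(1)),
    mean = vapply(sp, mean, numeric(1)),
    sd = vapply(sp, function(v) {
      if (length(v) > 1L) stats::sd(v) else NA_real_
    }, numeric(1)),
    stringsAsFactors = FALSE)
  perPatient <- perPatient[order(perPatient$mean), , drop = FALSE]
  perPatient$rank <- seq_len(nrow(perPatient))
  rownames(perPatient) <- NULL
  multi <- perPatient$nLesions > 1L
  list(
    perPatient = perPatient,
    summary = c(
      rangeOfMeans = diff(range(perPatient$mean)),
      meanWithinSD = if (any(multi)) mean(perPatient$sd[multi]) else NA_real_)
  )
}
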