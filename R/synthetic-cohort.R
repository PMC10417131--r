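# Synthetic cohorts with planted co-expression modules, subtypes,
# liver-like contamination, survival structure and multi-lesion patients.
# Expression is generated directly on the centralized log10 scale the
# pipeline consumes: module genes carry their module's per-sample activation,
# background genes sit at zero, and Gaussian noise is added at the patient
# and lesion level.

#' Describe a synthetic cohort
#'
#' Builds and validates the design object consumed by [generateCohort()].
#' All expression levels are in centralized log10 units.
#'
#' @param nGenes,nSamples Cohort dimensions.
#' @param subtypeProportions Named fractions summing to 1.
#' @param moduleSizes Named integer vector, genes per planted module.
#' @param moduleLevels Numeric matrix (modules x subtypes) of activation
#'   levels; missing entries default to 0.
#' @param contaminationModule Module acting as the liver-tissue signature.
#' @param contaminationFraction Fraction of samples (across all subtypes)
#'   with additional activation of the contamination module.
#' @param contaminationLevel Additive activation for contaminated samples.
#' @param activationSd Per-patient SD of module activation around the
#'   subtype level (biological variability of module activity).
#' @param noiseSd Per-gene Gaussian noise SD at the patient level.
#' @param intraPatientSd Per-gene Gaussian noise SD between lesions of the
#'   same patient.
#' @param lesionsPerPatient Named probability vector over lesion counts.
#' @param survivalBetas Named log-hazard coefficients per module.
#' @param censorFraction Probability that a sample's follow-up is censored.
#' @param seed Integer seed; identical designs give bit-identical cohorts.
#' @return A validated list of class `CohortDesign`.
#' @seealso [defaultCohortDesign()] for the shipped default design.
#' @export
cohortDesign <- function(nGenes, nSamples, subtypeProportions,
                         moduleSizes, moduleLevels,
                         contaminationModule = NA_character_,
                         contaminationFraction = 0,
                         contaminationLevel = 0,
                         activationSd = 0.25,
                         noiseSd = 0.4,
                         intraPatientSd = 0.05,
                         lesionsPerPatient = c("1" = 1),
                         survivalBetas = numeric(0),
                         censorFraction = 0.25,
                         seed = 1L) {
  if (!.isCount(nGenes) || !.isCount(nSamples)) {
    stop("nGenes and nSamples must be positive counts")
  }
  if (is.null(names(subtypeProportions)) ||
      abs(sum(subtypeProportions) - 1) > 1e-9) {
    stop("subtypeProportions must be named and sum to 1")
  }
  if (is.null(names(moduleSizes)) || any(moduleSizes < 1)) {
    stop("moduleSizes must be named positive counts")
  }
  if (sum(moduleSizes) > nGenes) {
    stop("module gene counts (", sum(moduleSizes),
         ") exceed nGenes (", nGenes, ")")
  }
  lev <- matrix(0, length(moduleSizes), length(subtypeProportions),
                dimnames = list(names(moduleSizes), names(subtypeProportions)))
  if (!missing(moduleLevels) && !is.null(moduleLevels)) {
    if (is.null(rownames(moduleLevels)) || is.null(colnames(moduleLevels))) {
      stop("moduleLevels must carry module and subtype dimnames")
    }
    lev[rownames(moduleLevels), colnames(moduleLevels)] <- moduleLevels
  }
  if (!is.na(contaminationModule) &&
      !contaminationModule %in% names(moduleSizes)) {
    stop("contaminationModule must name a planted module")
  }
  if (contaminationFraction < 0 || contaminationFraction > 1) {
    stop("contaminationFraction must be in [0, 1]")
  }
  if (length(survivalBetas) &&
      !all(names(survivalBetas) %in% names(moduleSizes))) {
    stop("survivalBetas must reference existing module labels")
  }
  if (censorFraction < 0 || censorFraction >= 1) {
    stop("censorFraction must be in [0, 1)")
  }
  if (is.null(names(lesionsPerPatient)) ||
      abs(sum(lesionsPerPatient) - 1) > 1e-9) {
    stop("lesionsPerPatient must be a named probability vector summing to 1")
  }
  structure(list(
    nGenes = as.integer(nGenes), nSamples = as.integer(nSamples),
    subtypeProportions = subtypeProportions,
    moduleSizes = stats::setNames(as.integer(moduleSizes), names(moduleSizes)),
    moduleLevels = lev,
    contaminationModule = contaminationModule,
    contaminationFraction = contaminationFraction,
    contaminationLevel = contaminationLevel,
    activationSd = activationSd, noiseSd = noiseSd,
    intraPatientSd = intraPatientSd,
    lesionsPerPatient = lesionsPerPatient,
    survivalBetas = survivalBetas,
    censorFraction = censorFraction,
    seed = as.integer(seed)
  ), class = "CohortDesign")
}

#' Default synthetic cohort design
#'
#' 6,000 genes, 120 samples, six planted modules (A-F) of 200-400 genes,
#' five tumor subtypes (S1-S5) plus a liver-like group (LIV). Each subtype
#' carries one dominant overexpression module; the epithelial-like (A) and
#' cycling-like (C) modules are under-expressed in the mesenchymal-like
#' subtype S5; module F is the liver signature, strongly active in LIV and
#' additionally activated in 35% of samples across all subtypes. The
#' default survival model puts a log-hazard of +0.7 on the activation of
#' module A, so high-A (S1-like) samples carry inferior prognosis and
#' low-A (S5-like) samples favorable prognosis.
#'
#' @param nSamples Number of samples (lesions).
#' @param seed Integer seed.
#' @param survivalBetas Named log-hazard coefficients per module.
#' @param nGenes Number of genes (default 6000; module sizes scale
#'   proportionally, mainly useful for quick smoke runs).
#' @return A `CohortDesign`.
#' @export
defaultCohortDesign <- function(nSamples = 120, seed = 1L,
                                survivalBetas = c(A = 0.7),
                                nGenes = 6000L) {
  lev <- matrix(0, 6, 6, dimnames = list(LETTERS[1:6],
                                         c("S1", "S2", "S3", "S4", "S5", "LIV")))
  lev["A", "S1"] <- 1.0; lev["A", "S5"] <- -0.8
  lev["B", "S2"] <- 1.0
  lev["C", "S4"] <- 1.0; lev["C", "S5"] <- -0.4
  lev["D", "S3"] <- 1.0
  lev["E", "S5"] <- 1.0
  lev["F", "LIV"] <- 1.5
  sizes <- c(A = 200L, B = 250L, C = 400L, D = 250L, E = 300L, F = 250L)
  if (nGenes != 6000L) {
    sizes <- stats::setNames(pmax(10L, as.integer(round(sizes * nGenes / 6000))),
                             names(sizes))
  }
  cohortDesign(
    nGenes = nGenes, nSamples = nSamples,
    subtypeProportions = c(S1 = 0.18, S2 = 0.18, S3 = 0.18, S4 = 0.18,
                           S5 = 0.18, LIV = 0.10),
    moduleSizes = sizes,
    moduleLevels = lev,
    contaminationModule = "F",
    contaminationFraction = 0.35,
    contaminationLevel = 1.0,
    activationSd = 0.25,
    noiseSd = 0.4,
    intraPatientSd = 0.045,
    lesionsPerPatient = c("1" = 0.7, "2" = 0.2, "3" = 0.1),
    survivalBetas = survivalBetas,
    censorFraction = 0.2,
    seed = seed
  )
}

#' Generate a synthetic cohort
#'
#' Draws patients with subtypes and lesion counts, per-patient module
#' activations (subtype level + Gaussian jitter), per-sample contamination
#' flags, and gene-level noise. Lesion expression is the patient latent
#' profile plus `N(0, intraPatientSd)`; the same design and seed always
#' reproduce the cohort bit-identically.
#'
#' @param design A `CohortDesign`.
#' @return A [SummarizedExperiment::SummarizedExperiment] with assay
#'   `exprs` (genes x samples, centralized log10 scale), `rowData` column
#'   `module` ("background" or module label), `colData` columns `subtype`,
#'   `patient`, `contaminated` and `trueLogHazard`, and the per-sample
#'   activation matrix plus the design under `metadata()`.
#' @export
generateCohort <- function(design) {
  stopifnot(inherits(design, "CohortDesign"))
  set.seed(design$seed)
  nS <- design$nSamples
  mods <- names(design$moduleSizes)
  nM <- length(mods)

  # patients: lesion counts then subtype, truncated at nSamples
  lesK <- as.integer(names(design$lesionsPerPatient))
  nles <- integer(0)
  while (sum(nles) < nS) {
    nles <- c(nles, sample(lesK, 1L, prob = design$lesionsPerPatient))
  }
  nP <- length(nles)
  patSubtype <- sample(names(design$subtypeProportions), nP, replace = TRUE,
                       prob = design$subtypeProportions)
  patient <- rep(seq_len(nP), nles)[seq_len(nS)]
  subtype <- patSubtype[patient]
  patientID <- sprintf("P%03d", patient)
  sampleID <- sprintf("sample%03d", seq_len(nS))

  # per-patient module activation = subtype level + jitter (shared by lesions)
  patAct <- design$moduleLevels[, patSubtype, drop = FALSE] +
    matrix(stats::rnorm(nM * nP, 0, design$activationSd), nM, nP)
  act <- t(patAct[, patient, drop = FALSE])        # samples x modules
  dimnames(act) <- list(sampleID, mods)

  contaminated <- rep(FALSE, nS)
  if (!is.na(design$contaminationModule) && design$contaminationFraction > 0) {
    contaminated <- stats::runif(nS) < design$contaminationFraction
    act[contaminated, design$contaminationModule] <-
      act[contaminated, design$contaminationModule] + design$contaminationLevel
  }

  geneModule <- rep("background", design$nGenes)
  geneModule[seq_len(sum(design$moduleSizes))] <-
    rep(mods, design$moduleSizes)
  geneID <- sprintf("gene%05d", seq_len(design$nGenes))

  # patient-level gene noise, shared across lesions of a patient
  patNoise <- matrix(stats::rnorm(design$nGenes * nP, 0, design$noiseSd),
                     design$nGenes, nP)
  x <- patNoise[, patient, drop = FALSE]
  if (design$intraPatientSd > 0) {
    x <- x + matrix(stats::rnorm(design$nGenes * nS, 0, design$intraPatientSd),
                    design$nGenes, nS)
  }
  for (m in mods) {
    idx <- which(geneModule == m)
    x[idx, ] <- x[idx, ] + rep(act[, m], each = length(idx))
  }
  dimnames(x) <- list(geneID, sampleID)

  trueLogHazard <- as.vector(act[, names(design$survivalBetas), drop = FALSE] %*%
                               design$survivalBetas)
  if (!length(design$survivalBetas)) trueLogHazard <- rep(0, nS)

  SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = x),
    rowData = S4Vectors::DataFrame(module = geneModule, row.names = geneID),
    colData = S4Vectors::DataFrame(
      sample = sampleID, subtype = subtype, patient = patientID,
      contaminated = contaminated, trueLogHazard = trueLogHazard,
      row.names = sampleID),
    metadata = list(design = design, activation = act)
  )
}

#' Ground truth of a synthetic cohort
#'
#' @param cohort A cohort from [generateCohort()].
#' @return List with `geneModule`, `samples` (annotation data.frame),
#'   `activation` (samples x modules) and `design`.
#' @export
cohortTruth <- function(cohort) {
  stopifnot(methods::is(cohort, "SummarizedExperiment"))
  list(
    geneModule = stats::setNames(
      SummarizedExperiment::rowData(cohort)$module, rownames(cohort)),
    samples = as.data.frame(SummarizedExperiment::colData(cohort)),
    activation = S4Vectors::metadata(cohort)$activation,
    design = S4Vectors::metadata(cohort)$design
  )
}

#' Attach survival outcomes to a cohort
#'
#' Event times are exponential with per-sample rate
#' `exp(sum(beta_m * activation_m))`; censoring is independent given the
#' sample: each sample is censored with probability `censorFraction` by an
#' independent exponential censoring time calibrated to that probability.
#'
#' @param cohort A cohort from [generateCohort()].
#' @param betas Named log-hazard coefficients per module; defaults to the
#'   design's `survivalBetas`.
#' @param censorFraction Per-sample censoring probability; defaults to the
#'   design value.
#' @param seed Integer seed for the survival draw.
#' @return A `data.frame` with columns `sample`, `patient`, `os_time`,
#'   `event` (1 = death observed, 0 = censored).
#' @export
attachSurvival <- function(cohort, betas = NULL, censorFraction = NULL,
                           seed = 1L) {
  truth <- cohortTruth(cohort)
  design <- truth$design
  if (is.null(betas)) betas <- design$survivalBetas
  if (is.null(censorFraction)) censorFraction <- design$censorFraction
  if (nrow(truth$samples) == 0L) stop("empty cohort")
  if (length(betas) && !all(names(betas) %in% colnames(truth$activation))) {
    stop("betas must reference existing module labels")
  }
  set.seed(seed)
  n <- nrow(truth$samples)
  lp <- if (length(betas)) {
    as.vector(truth$activation[, names(betas), drop = FALSE] %*% betas)
  } else rep(0, n)
  rate <- exp(lp)
  tt <- stats::rexp(n, rate = rate)
  event <- rep(1L, n)
  time <- tt
  if (censorFraction > 0) {
    # exponential censoring with P(C < T) = censorFraction for each sample
    crate <- rate * censorFraction / (1 - censorFraction)
    cc <- stats::rexp(n, rate = crate)
    event <- as.integer(tt <= cc)
    time <- pmin(tt, cc)
  }
  data.frame(sample = truth$samples$sample, patient = truth$samples$patient,
             os_time = time, event = event, stringsAsFactors = FALSE)
}

#' Generate a cohort with a planted one-dimensional gradient
#'
#' Samples receive a latent position t in [0, 1]; one module's activation
#' increases linearly with t and a second module's decreases, so the cohort
#' forms a noiseless-to-noisy 1-D path in expression space. Used to
#' validate trajectory recovery.
#'
#' @param nGenes,nSamples Cohort dimensions.
#' @param moduleSize Genes per gradient module.
#' @param amplitude Activation range (level runs from -amplitude/2 to
#'   +amplitude/2 across the gradient).
#' @param noiseSd Per-gene Gaussian noise SD.
#' @param seed Integer seed.
#' @return A `SummarizedExperiment` with `colData` column `position`.
#' @export
generateGradientCohort <- function(nGenes = 2000, nSamples = 100,
                                   moduleSize = 300, amplitude = 2,
                                   noiseSd = 0.4, seed = 1L) {
  stopifnot(2 * moduleSize <= nGenes)
  set.seed(seed)
  pos <- stats::runif(nSamples)
  sampleID <- sprintf("sample%03d", seq_len(nSamples))
  geneID <- sprintf("gene%05d", seq_len(nGenes))
  geneModule <- rep("background", nGenes)
  geneModule[seq_len(moduleSize)] <- "G1"
  geneModule[moduleSize + seq_len(moduleSize)] <- "G2"
  x <- matrix(stats::rnorm(nGenes * nSamples, 0, noiseSd), nGenes, nSamples,
              dimnames = list(geneID, sampleID))
  a1 <- amplitude * (pos - 0.5)
  x[geneModule == "G1", ] <- x[geneModule == "G1", ] +
    rep(a1, each = moduleSize)
  x[geneModule == "G2", ] <- x[geneModule == "G2", ] -
    rep(a1, each = moduleSize)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = x),
    rowData = S4Vectors::DataFrame(module = geneModule, row.names = geneID),
    colData = S4Vectors::DataFrame(sample = sampleID, position = pos,
                                   row.names = sampleID)
  )
}

#' Write a cohort to disk as plain-text files
#'
#' Writes the expression matrix, sample annotation and survival table as
#' TSV and the planted module gene lists as GMT, in formats that
#' round-trip losslessly through the package readers.
#'
#' @param dir Output directory (created if needed).
#' @param cohort A cohort from [generateCohort()].
#' @param survival Optional survival table from [attachSurvival()].
#' @return Invisibly, the named vector of written paths.
#' @export
writeCohort <- function(dir, cohort, survival = NULL) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    stop("cannot create directory: ", dir)
  }
  truth <- cohortTruth(cohort)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             annotation = file.path(dir, "annotation.tsv"),
             modules = file.path(dir, "modules.gmt"))
  writeExpressionMatrix(.getExprs(cohort), paths[["expression"]])
  ann <- truth$samples[, c("sample", "subtype", "patient")]
  utils::write.table(ann, paths[["annotation"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  sets <- split(names(truth$geneModule), truth$geneModule)
  sets <- sets[setdiff(names(sets), "background")]
  writeGMT(sets, paths[["modules"]],
           descriptions = paste("planted module", names(sets)))
  if (!is.null(survival)) {
    paths <- c(paths, survival = file.path(dir, "survival.tsv"))
    utils::write.table(
      survival[, c("sample", "os_time", "event")], paths[["survival"]],
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(paths)
}
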