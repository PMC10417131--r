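# Shared fixtures and independent oracles. Heavy fixtures (full-size
# trained maps) are built lazily and cached for the session.

.fixtureCache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixtureCache)) {
    assign(key, builder(), envir = .fixtureCache)
  }
  get(key, envir = .fixtureCache)
}

# A SOMModel with hand-set prototypes for arithmetic-level tests.
tinySOM <- function(width = 2, height = 2, prototypes = NULL,
                    assignment = NULL, samples = 3) {
  u <- width * height
  if (is.null(prototypes)) {
    prototypes <- matrix(seq_len(u * samples), u, samples)
  }
  if (is.null(colnames(prototypes))) {
    colnames(prototypes) <- sprintf("s%02d", seq_len(ncol(prototypes)))
  }
  if (is.null(assignment)) {
    assignment <- stats::setNames(rep(1L, 3), c("g1", "g2", "g3"))
  }
  methods::new("SOMModel",
    gridWidth = as.integer(width), gridHeight = as.integer(height),
    prototypes = prototypes, assignment = assignment,
    epochs = 1L, radiusSchedule = 1, seed = 1L, qe = 0)
}

# Brute-force signed wTO by direct triple-loop formula evaluation.
wtoBruteForce <- function(profiles) {
  a <- stats::cor(t(profiles))
  n <- nrow(a)
  w <- matrix(0, n, n, dimnames = dimnames(a))
  k <- numeric(n)
  for (i in seq_len(n)) {
    for (kk in seq_len(n)) if (kk != i) k[i] <- k[i] + abs(a[i, kk])
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { w[i, j] <- 1; next }
    num <- a[i, j]
    for (kk in seq_len(n)) {
      if (kk != i && kk != j) num <- num + a[i, kk] * a[kk, j]
    }
    w[i, j] <- num / (min(k[i], k[j]) + 1 - abs(a[i, j]))
  }
  w
}

# Brute-force AUC by concordant-pair counting (ties count 1/2).
aucBruteForce <- function(scores, positive) {
  pos <- scores[positive]
  neg <- scores[!positive]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Small trained map on a cohort with planted structure (used by several
# unit tests; ~3 s).
smallFit <- function() {
  cached("smallFit", function() {
    design <- defaultCohortDesign(nSamples = 60, seed = 42, nGenes = 1500)
    cohort <- generateCohort(design)
    x <- centralize(SummarizedExperiment::assay(cohort))
    model <- trainSOM(x, gridWidth = 20, gridHeight = 20, epochs = 15,
                      seed = 42)
    truth <- cohortTruth(cohort)
    list(cohort = cohort, x = x, model = model, truth = truth,
         subtype = stats::setNames(truth$samples$subtype,
                                   truth$samples$sample))
  })
}

# Full-size fits used by the acceptance suite.
fullFit120 <- function(seed = 1) {
  cached(paste0("fullFit120_", seed), function() {
    design <- defaultCohortDesign(nSamples = 120, seed = seed)
    cohort <- generateCohort(design)
    x <- centralize(SummarizedExperiment::assay(cohort))
    model <- trainSOM(x, 50, 50, epochs = 30, seed = seed)
    truth <- cohortTruth(cohort)
    subtype <- stats::setNames(truth$samples$subtype, truth$samples$sample)
    maps <- supportingMaps(model, groups = subtype)
    spots <- detectSpots(model, maps$groupSummary)
    list(cohort = cohort, x = x, model = model, truth = truth,
         subtype = subtype, maps = maps, spots = spots)
  })
}

fullFit200 <- function() {
  cached("fullFit200", function() {
    design <- defaultCohortDesign(nSamples = 200, seed = 11)
    cohort <- generateCohort(design)
    x <- centralize(SummarizedExperiment::assay(cohort))
    model <- trainSOM(x, 50, 50, epochs = 30, seed = 11)
    truth <- cohortTruth(cohort)
    list(cohort = cohort, x = x, model = model, truth = truth)
  })
}

# Jaccard between a detected spot gene list and a planted module.
bestJaccard <- function(spots, moduleGenes) {
  if (length(spotLabels(spots)) == 0L) return(0)
  max(vapply(spotGenes(spots), function(sg) {
    length(intersect(sg, moduleGenes)) / length(union(sg, moduleGenes))
  }, numeric(1)))
}

bestSpotFor <- function(spots, moduleGenes) {
  which.max(vapply(spotGenes(spots), function(sg) {
    length(intersect(sg, moduleGenes)) / length(union(sg, moduleGenes))
  }, numeric(1)))
}

moduleGenesOf <- function(truth, label) {
  names(truth$geneModule)[truth$geneModule == label]
}
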