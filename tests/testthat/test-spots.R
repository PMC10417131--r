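# Constructed-map fixtures: an 8x8 grid with hand-placed elevated blocks.
blockMap <- function(cols, rows, value = 1, width = 8, height = 8,
                     base = NULL) {
  map <- base
  if (is.null(map)) map <- rep(0, width * height)
  coords <- cbind(col = (seq_along(map) - 1L) %% width,
                  row = (seq_along(map) - 1L) %/% width)
  map[coords[, "col"] %in% cols & coords[, "row"] %in% rows] <- value
  map
}

test_that("spot detection finds constructed blocks and filters small ones", {
  m <- tinySOM(8, 8, prototypes = matrix(0, 64, 3),
               assignment = stats::setNames(rep(1L, 3), c("g1", "g2", "g3")))
  one <- blockMap(2:4, 2:4)
  s <- detectSpots(m, one, thresholdQuantile = 0.8)
  expect_equal(spotLabels(s), "A")
  expect_length(spotPixels(s)[["A"]], 9L)

  two <- blockMap(6:7, 6:7, value = 2, base = one)
  s2 <- detectSpots(m, two, thresholdQuantile = 0.7)
  expect_equal(spotLabels(s2), c("A", "B"))
  # labels ordered by descending peak height
  expect_equal(max(two[spotPixels(s2)[["A"]]]), 2)
  expect_length(spotPixels(s2)[["B"]], 9L)
  expect_length(spotPixels(s2)[["A"]], 4L)

  tiny <- blockMap(1:2, 1, value = 1)
  expect_message(s3 <- detectSpots(m, tiny, thresholdQuantile = 0.9,
                                   minPixels = 4),
                 "no spots")
  expect_length(spotLabels(s3), 0L)
})

test_that("watershed splitting separates touching peaks; Inf tolerance merges", {
  m <- tinySOM(8, 8, prototypes = matrix(0, 64, 3))
  # two peaks joined by a lower bridge, all above threshold
  map <- blockMap(1:2, 3:4, value = 1)
  map <- blockMap(5:6, 3:4, value = 1.2, base = map)
  map <- blockMap(3:4, 3:4, value = 0.4, base = map)
  split <- detectSpots(m, map, thresholdQuantile = 0.5, tolerance = 0.1,
                       minPixels = 4)
  expect_length(spotLabels(split), 2L)
  merged <- detectSpots(m, map, thresholdQuantile = 0.5, tolerance = Inf,
                        minPixels = 4)
  expect_length(spotLabels(merged), 1L)
})

test_that("per-portrait spot counts follow the detection rule", {
  m <- tinySOM(8, 8, prototypes = matrix(0, 64, 3))
  expect_equal(countSampleSpots(rep(0, 64), m), 0L)
  two <- blockMap(6:7, 6:7, value = 2, base = blockMap(1:3, 1:3))
  expect_equal(countSampleSpots(two, m, thresholdQuantile = 0.7), 2L)
  expect_equal(countSampleSpots(two + 11, m, thresholdQuantile = 0.7), 2L)
})

test_that("spot expression is the pixel-set mean of metagene profiles", {
  pr <- matrix(c(1, 2, 3, 4,
                 10, 20, 30, 40), 4, 2,
               dimnames = list(NULL, c("sA", "sB")))
  m <- tinySOM(2, 2, prototypes = pr)
  expect_equal(spotExpression(m, 2L), c(sA = 2, sB = 20))
  expect_equal(spotExpression(m, c(1L, 4L)), c(sA = 2.5, sB = 25))
  expect_equal(spotExpression(m, 1:4), colMeans(pr))
})

test_that("spot AUC matches hand counts and flags degenerate classes", {
  expect_equal(spotAUC(c(3, 2, 1), c("a", "a", "b"), "a"), 1)
  expect_equal(spotAUC(c(2, 0, 1), c("a", "a", "b"), "a"), 0.5)
  expect_error(spotAUC(c(1, 2), c("a", "a"), "a"), "both classes")
  expect_error(spotAUC(c(1, 2), c("a", "a"), "b"), "not present")
  # under-expression markers report AUC < 0.5 as-is
  expect_equal(spotAUC(c(1, 2, 3), c("a", "b", "b"), "a"), 0)
})

test_that("AUC equals brute-force pair counting on random data", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(10:50, 1)
    scores <- sample(seq_len(20), n, replace = TRUE)  # with ties
    pos <- seq_len(n) %in% sample(n, sample(2:(n - 2), 1))
    expect_identical(somscape:::.rankAUC(scores, pos),
                     aucBruteForce(scores, pos))
  }
})

test_that("ternary coordinates clip, normalize and hit the centroid", {
  expect_equal(ternaryCoordinates(c(1, 1, 1)), rep(1 / 3, 3))
  expect_equal(ternaryCoordinates(c(2, 0, 0)), c(1, 0, 0))
  expect_equal(ternaryCoordinates(c(-1, 1, 1)), c(0, 0.5, 0.5))
  expect_equal(ternaryCoordinates(c(0, 0, 0)), rep(1 / 3, 3))
  mat <- ternaryCoordinates(rbind(c(1, 2, 1), c(-3, 0, 0)))
  expect_equal(rowSums(mat), c(1, 1))
  expect_equal(mat[2, ], rep(1 / 3, 3))
})

test_that("wTO equals the brute-force formula and its limits", {
  set.seed(3)
  for (rep in 1:3) {
    profiles <- matrix(rnorm(6 * 25), 6, 25,
                       dimnames = list(paste0("S", 1:6), NULL))
    w <- wtoMatrix(profiles)
    expect_lt(max(abs(w - wtoBruteForce(profiles))), 1e-10)
    expect_equal(w, t(w))
  }
  # two perfectly correlated spots
  two <- rbind(A = 1:10, B = 2 * (1:10) + 3)
  expect_equal(wtoMatrix(two)[1, 2], 1)
  bad <- rbind(A = 1:10, B = rep(2, 10))
  expect_error(wtoMatrix(bad), "constant spot profile.*B")
})

test_that("contamination split recovers a bimodal profile", {
  prof <- stats::setNames(c(-1, -1, -1, 2, 2), paste0("s", 1:5))
  res <- contaminationSplit(prof)
  expect_equal(res$fractionHigh, 0.4)
  expect_equal(unname(res$labels == "high"), c(FALSE, FALSE, FALSE, TRUE, TRUE))
  # monotone affine invariance
  res2 <- contaminationSplit(prof * 3 + 7)
  expect_identical(res$labels, res2$labels)
  expect_warning(res3 <- contaminationSplit(rep(1, 4)), "constant")
  expect_equal(res3$fractionHigh, 0)
  expect_error(contaminationSplit(1), "at least 2")
})

test_that("a planted bimodal contamination module is split near its fraction", {
  design <- cohortDesign(
    nGenes = 800, nSamples = 80,
    subtypeProportions = c(S1 = 0.5, S2 = 0.5),
    moduleSizes = c(A = 100, F = 120),
    moduleLevels = matrix(c(1, 0), 2, 1, dimnames = list(c("A", "F"), "S1")),
    contaminationModule = "F", contaminationFraction = 0.35,
    contaminationLevel = 1.5, activationSd = 0.15, noiseSd = 0.4,
    intraPatientSd = 0, seed = 12)
  co <- generateCohort(design)
  truth <- cohortTruth(co)
  x <- centralize(SummarizedExperiment::assay(co))
  fGenes <- moduleGenesOf(truth, "F")
  res <- contaminationSplit(colMeans(x[fGenes, ]))
  expect_gt(mean((res$labels == "high") == truth$samples$contaminated), 0.9)
  expect_lt(abs(res$fractionHigh - mean(truth$samples$contaminated)), 0.1)
})

test_that("samples order within groups by the chosen spot's expression", {
  prof <- rbind(A = c(3, 1, 2, 9, 8, 7), B = rnorm(6))
  colnames(prof) <- sprintf("s%d", 1:6)
  spots <- methods::new("SpotCollection",
    labels = c("A", "B"), pixels = list(1L, 2L),
    genes = list("g1", "g2"), profiles = prof, map = 0,
    gridWidth = 2L, gridHeight = 1L, threshold = 0, minPixels = 1L)
  groups <- stats::setNames(rep(c("x", "y"), each = 3), colnames(prof))
  ord <- orderSamplesBySpot(spots, "A", groups)
  expect_equal(ord, c("s2", "s3", "s1", "s6", "s5", "s4"))
})
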