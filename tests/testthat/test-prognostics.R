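# Survival fixtures are built in code: a small grid whose prototypes
# carry one risk-linked metagene plus null metagenes.

riskFixture <- function(n = 120, seed = 21) {
  set.seed(seed)
  grp <- rep(c(0, 1), length.out = n)                  # risk indicator
  samples <- sprintf("s%03d", seq_len(n))
  pr <- rbind(
    risk = grp - mean(grp) + 0.01 * rnorm(n),          # tracks the risk group
    null1 = rnorm(n), null2 = rnorm(n), null3 = rnorm(n))
  colnames(pr) <- samples
  asn <- stats::setNames(sample(1:4, 40, replace = TRUE),
                         sprintf("g%02d", 1:40))
  model <- tinySOM(2, 2, prototypes = pr, assignment = asn)
  time <- stats::rexp(n, rate = exp(log(2) * grp))     # true HR = 2
  surv <- data.frame(sample = samples, os_time = time,
                     event = rep(1L, n))
  list(model = model, surv = surv, grp = grp)
}

test_that("hr maps recover a planted hazard ratio and mask small groups", {
  fx <- riskFixture()
  hm <- hrMap(fx$model, fx$surv, minGroup = 5)
  expect_false(maskedPixels(hm)[1])
  expect_gt(hrValues(hm)[1], 1.4)
  expect_lt(hrValues(hm)[1], 2.8)
  # null metagenes sit near HR 1
  expect_true(all(hrValues(hm)[2:4] > 0.5 & hrValues(hm)[2:4] < 2))

  # cross-check one pixel against the coxph formula interface
  grp <- prototypes(fx$model)[1, ] > 0
  ref <- survival::coxph(
    survival::Surv(fx$surv$os_time, fx$surv$event) ~ grp, ties = "efron")
  expect_equal(log(hrValues(hm)[1]), unname(stats::coef(ref)),
               tolerance = 1e-8)

  # a pixel with a tiny high-expression arm is masked
  pr <- prototypes(fx$model)
  pr["null3", ] <- c(rep(1, 3), rep(-1, ncol(pr) - 3))
  m2 <- tinySOM(2, 2, prototypes = pr, assignment = fx$model@assignment)
  hm2 <- hrMap(m2, fx$surv, minGroup = 5)
  expect_true(maskedPixels(hm2)[4])
  expect_true(is.na(hrValues(hm2)[4]))

  allCens <- fx$surv
  allCens$event <- 0L
  expect_error(hrMap(fx$model, allCens), "censored")
})

test_that("extreme metagenes take the argmax/argmin with documented ties", {
  asn <- stats::setNames(c(1L, 1L, 2L, 3L, 4L, 4L), paste0("g", 1:6))
  model <- tinySOM(2, 2, prototypes = matrix(rnorm(12), 4, 3),
                   assignment = asn)
  hm <- methods::new("HRMap", hr = c(0.5, 1.0, 2.0, 1.0),
                     nHigh = rep(10L, 4), masked = rep(FALSE, 4),
                     mode = "gt-mean", minGroup = 5L,
                     gridWidth = 2L, gridHeight = 2L)
  sk <- extremeMetagenes(hm, model, minGenes = 1, smoothRadius = 0)
  expect_equal(sk@maxPixel, 3L)
  expect_equal(sk@minPixel, 1L)
  expect_equal(sk@maxHR, 2.0)
  expect_setequal(sk@minGenes, c("g1", "g2"))

  # tie on the maximum resolves to the lower linear index
  hmTie <- methods::new("HRMap", hr = c(2.0, 1.0, 2.0, 1.0),
                        nHigh = rep(10L, 4), masked = rep(FALSE, 4),
                        mode = "gt-mean", minGroup = 5L,
                        gridWidth = 2L, gridHeight = 2L)
  skTie <- extremeMetagenes(hmTie, model, minGenes = 1, smoothRadius = 0)
  expect_equal(skTie@maxPixel, 1L)

  # neighborhood padding stops exactly at the requested count
  skPad <- extremeMetagenes(hm, model, minGenes = 4, smoothRadius = 0)
  expect_length(skPad@maxGenes, 4L)
  expect_true("g4" %in% skPad@maxGenes)  # the pixel's own gene comes first

  hmMasked <- methods::new("HRMap", hr = rep(NA_real_, 4),
                           nHigh = rep(1L, 4), masked = rep(TRUE, 4),
                           mode = "gt-mean", minGroup = 5L,
                           gridWidth = 2L, gridHeight = 2L)
  expect_error(extremeMetagenes(hmMasked, model), "fully masked")
})

test_that("the risk score is the gene-list mean difference, antisymmetric", {
  x <- matrix(0, 4, 3, dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
  x[c("g1", "g2"), ] <- 1
  x[c("g3", "g4"), ] <- -1
  sk <- methods::new("PrognosticScore",
    maxPixel = 1L, minPixel = 2L,
    maxGenes = c("g1", "g2"), minGenes = c("g3", "g4"),
    maxHR = 2, minHR = 0.5, scores = numeric(0))
  sc <- deltaHRScore(x, sk)
  expect_equal(unname(sampleScores(sc)), rep(2, 3))

  # identical lists give zero
  skSame <- methods::initialize(sk, minGenes = c("g1", "g2"), minHR = 2)
  expect_equal(unname(sampleScores(deltaHRScore(x, skSame))), rep(0, 3))

  # adding a constant to the maxHR genes shifts the score by that constant
  x2 <- x
  x2[c("g1", "g2"), ] <- x2[c("g1", "g2"), ] + 3
  expect_equal(sampleScores(deltaHRScore(x2, sk)),
               sampleScores(sc) + 3)

  # swapping the lists negates the score exactly
  skSwap <- methods::initialize(sk, maxGenes = sk@minGenes,
                                minGenes = sk@maxGenes,
                                maxHR = 2, minHR = 0.5)
  expect_identical(sampleScores(deltaHRScore(x, skSwap)),
                   -sampleScores(sc))

  skEmpty <- methods::initialize(sk, maxGenes = "absent")
  expect_error(deltaHRScore(x, skEmpty), "absent from the matrix")
})

test_that("risk-group splits have exact sizes and a null log-rank of zero", {
  set.seed(31)
  n <- 100
  scores <- stats::setNames(rnorm(n), sprintf("s%03d", 1:n))
  surv <- data.frame(sample = names(scores),
                     os_time = rep(c(1, 2, 3, 4), 25),
                     event = rep(1L, n))
  res <- splitRiskGroups(scores, surv, percentile = 25)
  expect_equal(sum(res$groups == "high", na.rm = TRUE), 25L)
  expect_equal(sum(res$groups == "low", na.rm = TRUE), 25L)

  # groups carrying literally identical survival data -> log-rank 0
  sameScores <- stats::setNames(1:8, sprintf("t%02d", 1:8))
  sameSurv <- data.frame(sample = names(sameScores),
                         os_time = rep(c(1, 2, 3, 4), 2),
                         event = rep(1L, 8))
  resSame <- splitRiskGroups(sameScores, sameSurv, percentile = 50)
  expect_lt(resSame$chisq, 1e-10)
  expect_equal(resSame$p, 1, tolerance = 1e-6)
  expect_error(splitRiskGroups(scores, surv, percentile = 60), "\\(0, 50]")
  expect_error(splitRiskGroups(scores[1:4], surv[1:4, ], percentile = 25),
               "fewer than 2")
})

test_that("a planted score-hazard link is detected by the split", {
  set.seed(41)
  n <- 200
  scores <- stats::setNames(rnorm(n), sprintf("s%03d", 1:n))
  hits <- 0
  for (i in 1:20) {
    time <- stats::rexp(n, rate = exp(0.7 * scores))
    surv <- data.frame(sample = names(scores), os_time = time,
                       event = rep(1L, n))
    res <- splitRiskGroups(scores, surv, percentile = 25)
    hits <- hits + (res$p < 0.01)
  }
  expect_gte(hits, 18)
})

test_that("patient heterogeneity summarizes lesion scores per patient", {
  scores <- c(p1a = 1, p1b = 3, p2a = 2, p2b = 2, p3 = 9)
  patients <- c(p1a = "P1", p1b = "P1", p2a = "P2", p2b = "P2", p3 = "P3")
  het <- patientHeterogeneity(scores, patients)
  tab <- het$perPatient
  expect_equal(tab$mean[tab$patient == "P1"], 2)
  expect_equal(tab$sd[tab$patient == "P1"], sqrt(2))
  expect_equal(tab$sd[tab$patient == "P2"], 0)
  expect_true(is.na(tab$sd[tab$patient == "P3"]))
  expect_equal(tab$patient[order(tab$rank)], c("P1", "P2", "P3"))
  expect_equal(unname(het$summary["rangeOfMeans"]), 7)
  expect_equal(unname(het$summary["meanWithinSD"]), mean(c(sqrt(2), 0)))
})

test_that("the spot-based score variant substitutes spot gene lists", {
  prof <- rbind(A = 1:4, E = 4:1)
  colnames(prof) <- sprintf("s%d", 1:4)
  spots <- methods::new("SpotCollection",
    labels = c("A", "E"), pixels = list(1L, 2L),
    genes = list(c("g1", "g2"), c("g3", "g4")), profiles = prof, map = 0,
    gridWidth = 2L, gridHeight = 1L, threshold = 0, minPixels = 1L)
  sk <- spotScoreSkeleton(spots, highSpot = "A", lowSpot = "E")
  expect_equal(sk@maxGenes, c("g1", "g2"))
  expect_equal(sk@minGenes, c("g3", "g4"))
  x <- matrix(c(1, 1, 0, 0), 4, 2,
              dimnames = list(paste0("g", 1:4), c("sa", "sb")))
  expect_equal(unname(sampleScores(deltaHRScore(x, sk))), c(1, 1))
  expect_error(spotScoreSkeleton(spots, "A", "Z"))
})
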