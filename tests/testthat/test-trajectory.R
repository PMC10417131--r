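# Geometric fixtures are built directly in reduced "metagene" space so the
# tree shape is known by construction.

pathFixture <- function(n = 40, jitterSd = 0.02, seed = 1) {
  set.seed(seed)
  t <- seq(0, 1, length.out = n)
  x <- cbind(t, jitterSd * rnorm(n), jitterSd * rnorm(n))
  rownames(x) <- sprintf("s%03d", seq_len(n))
  list(x = x, t = t)
}

test_that("a 1-D gradient yields a path with monotone pseudotime", {
  fx <- pathFixture()
  tree <- fitPrincipalTree(fx$x, nComponents = 2, nNodes = 8, seed = 1)
  g <- somscape:::.treeGraph(tree)
  expect_equal(sum(igraph::degree(g) == 1), 2L)
  # root at the t=0 end
  rootNode <- tree@sampleNode[["s001"]]
  tree <- assignSegmentsPseudotime(tree, root = rootNode)
  expect_equal(nrow(tree@segments), 1L)
  expect_gt(stats::cor(pseudotimes(tree), fx$t, method = "spearman"), 0.95)
  expect_equal(min(pseudotimes(tree)), 0)
})

test_that("a three-armed star yields three leaves and three segments", {
  set.seed(2)
  arm <- function(dx, dy) {
    t <- seq(0.15, 1, length.out = 20)
    cbind(t * dx, t * dy) + 0.01 * matrix(rnorm(40), 20, 2)
  }
  x <- rbind(matrix(0.01 * rnorm(10), 5, 2),
             arm(1, 0), arm(-1, 0.2), arm(0, -1))
  rownames(x) <- sprintf("s%03d", seq_len(nrow(x)))
  tree <- fitPrincipalTree(x, nComponents = 2, nNodes = 12, seed = 3)
  g <- somscape:::.treeGraph(tree)
  expect_equal(sum(igraph::degree(g) == 1), 3L)
  tree <- assignSegmentsPseudotime(tree, root = which(igraph::degree(g) == 1)[1])
  expect_equal(nrow(tree@segments), 3L)
  expect_setequal(unique(tree@segment), c("Seg1", "Seg2", "Seg3"))
})

test_that("tree invariants and determinism hold; duplicates co-locate", {
  fx <- pathFixture(seed = 4)
  x <- rbind(fx$x, dupA = fx$x[10, ], dupB = fx$x[10, ])
  t1 <- fitPrincipalTree(x, nComponents = 2, nNodes = 8, seed = 5)
  t2 <- fitPrincipalTree(x, nComponents = 2, nNodes = 8, seed = 5)
  expect_identical(t1@sampleNode, t2@sampleNode)
  expect_equal(nrow(t1@edges), nrow(t1@nodes) - 1L)
  expect_equal(t1@sampleNode[["dupA"]], t1@sampleNode[["dupB"]])
  t1 <- assignSegmentsPseudotime(t1, root = 1L)
  expect_equal(pseudotimes(t1)[["dupA"]], pseudotimes(t1)[["dupB"]])
  expect_error(fitPrincipalTree(fx$x, nNodes = 100, seed = 1), "more nodes")
  expect_error(fitPrincipalTree(fx$x, nComponents = 40, nNodes = 5, seed = 1),
               "below the sample count")
})

test_that("root selection by spot expression picks the high-expression leaf", {
  fx <- pathFixture(seed = 6)
  tree <- fitPrincipalTree(fx$x, nComponents = 2, nNodes = 8, seed = 6)
  prof <- matrix(fx$t, 1, length(fx$t),
                 dimnames = list("E", rownames(fx$x)))
  spots <- methods::new("SpotCollection",
    labels = "E", pixels = list(1L), genes = list("g1"),
    profiles = prof, map = 0, gridWidth = 1L, gridHeight = 1L,
    threshold = 0, minPixels = 1L)
  tree <- assignSegmentsPseudotime(tree, spots = spots, rootSpot = "E")
  # the root leaf hosts the highest-t samples, so pseudotime anticorrelates
  expect_lt(stats::cor(pseudotimes(tree), fx$t, method = "spearman"), -0.9)
  expect_error(assignSegmentsPseudotime(tree, spots = spots,
                                        rootSpot = "Z"), "unknown spot")
})

test_that("overlap coefficient follows its definition", {
  expect_equal(overlapCoefficient(1:4, 1:4), 1)
  expect_equal(overlapCoefficient(1:3, 4:6), 0)
  expect_equal(overlapCoefficient(1:4, c(3, 4, 7, 8, 9, 10, 11)), 0.5)
  # symmetry and containment
  expect_equal(overlapCoefficient(1:3, 1:10), 1)
  expect_equal(overlapCoefficient(1:10, 1:3), 1)
  expect_error(overlapCoefficient(integer(0), 1:3), "nonempty")
})

test_that("segment profiles are pseudotime-ordered with conserved flow", {
  fx <- pathFixture(seed = 8)
  tree <- fitPrincipalTree(fx$x, nComponents = 2, nNodes = 8, seed = 8)
  tree <- assignSegmentsPseudotime(tree, root = tree@sampleNode[["s001"]])
  n <- nrow(fx$x)
  prof <- matrix(rnorm(2 * n), 2, n,
                 dimnames = list(c("A", "B"), rownames(fx$x)))
  spots <- methods::new("SpotCollection",
    labels = c("A", "B"), pixels = list(1L, 2L),
    genes = list("g1", "g2"), profiles = prof, map = 0,
    gridWidth = 2L, gridHeight = 1L, threshold = 0, minPixels = 1L)
  pr2 <- matrix(rnorm(2 * n), 2, n, dimnames = list(NULL, rownames(fx$x)))
  model <- tinySOM(2, 1, prototypes = pr2,
                   assignment = stats::setNames(c(1L, 2L), c("g1", "g2")))
  subtype <- stats::setNames(rep(c("X", "Y"), length.out = n),
                             rownames(fx$x))
  res <- segmentSpotProfiles(tree, model, spots, subtypes = subtype)
  tab <- res$profiles[[1]]
  expect_false(is.unsorted(tab$pseudotime))
  expect_equal(unname(rowSums(res$flow)), unname(table(subtype)),
               ignore_attr = TRUE)
  expect_equal(sum(res$flow), n)
  expect_equal(length(res$meanPortraits), nrow(tree@segments))
})

test_that("Newick export writes one leaf label per tree leaf", {
  fx <- pathFixture(seed = 9)
  tree <- fitPrincipalTree(fx$x, nComponents = 2, nNodes = 6, seed = 9)
  nwk <- treeNewick(tree)
  expect_match(nwk, ";$")
  ph <- ape::read.tree(text = nwk)
  expect_equal(ape::Ntip(ph) + ph$Nnode, nrow(tree@nodes))
})

test_that("segment profiles append the optional score column", {
  fx <- pathFixture(seed = 11)
  tree <- fitPrincipalTree(fx$x, nComponents = 2, nNodes = 6, seed = 11)
  tree <- assignSegmentsPseudotime(tree, root = tree@sampleNode[["s001"]])
  n <- nrow(fx$x)
  prof <- matrix(rnorm(n), 1, n, dimnames = list("A", rownames(fx$x)))
  spots <- methods::new("SpotCollection",
    labels = "A", pixels = list(1L), genes = list("g1"),
    profiles = prof, map = 0, gridWidth = 1L, gridHeight = 1L,
    threshold = 0, minPixels = 1L)
  model <- tinySOM(1, 1, prototypes = matrix(rnorm(n), 1, n,
                                             dimnames = list(NULL, rownames(fx$x))))
  scores <- stats::setNames(rnorm(n), rownames(fx$x))
  res <- segmentSpotProfiles(tree, model, spots, scores = scores)
  tab <- res$profiles[[1]]
  expect_true("score" %in% colnames(tab))
  expect_equal(tab$score, unname(scores[tab$sample]))
  expect_error(segmentSpotProfiles(tree, model, spots,
                                   scores = scores[-1]), "missing")
})
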