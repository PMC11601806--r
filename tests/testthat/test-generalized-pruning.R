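test_that("tree counts through edges match enumeration exactly", {
  d <- sdagFromTopologies(unionPairTrees(TRUE), taxa7)
  tops <- enumerateTopologies(d)
  for (e in sdagEdges(d)$key) {
    inTe <- sum(vapply(tops, function(tp)
      e %in% topologyToEdges(tp, taxa7)$key, TRUE))
    expect_equal(countTreesThroughEdge(d, e), inTe)
  }
  ## the central-chain edge {{3},{4,5,6}} -> {{4},{5,6}} lies in 2 of the 4
  e2 <- paste("0001000|0000111", "right", "0000100|0000011")
  expect_equal(countTreesThroughEdge(d, e2), 2)
  expect_error(countTreesThroughEdge(d, "bogus"), "not in sDAG")
  ## partition identity: per-(node, clade) counts sum over outgoing edges
  ed <- sdagEdges(d)
  for (slot in unique(paste(ed$parent, ed$which))) {
    rows <- which(paste(ed$parent, ed$which) == slot)
    through <- sum(vapply(tops, function(tp) {
      keys <- topologyToEdges(tp, taxa7)$key
      any(ed$key[rows] %in% keys)
    }, TRUE))
    expect_equal(sum(vapply(ed$key[rows], countTreesThroughEdge, 0, d = d)),
                 through)
  }
})

test_that("single-topology sDAGs degenerate to the tree likelihood", {
  set.seed(61)
  phy <- randomRootedTopology(5, brlenMean = 0.2)
  aln <- simulateJCAlignment(phy, 40)
  d <- sdagFromTopologies(phy)
  ll <- treeLogLikelihood(phy, aln)
  g <- gpLikelihood(d, sdagEdges(d)$key, aln)
  expect_true(max(abs(g - ll)) < 1e-9)
  expect_true(all(vapply(sdagEdges(d)$key, countTreesThroughEdge, 0, d = d) == 1))
  expect_equal(gpLikelihoodBruteforce(d, sdagEdges(d)$key[3], aln), ll,
               tolerance = 1e-10)
})

test_that("the dynamic program equals brute-force enumeration", {
  set.seed(71)
  maxdiff <- 0
  for (rep in 1:30) {
    n <- sample(4:6, 1)
    k <- sample(2:4, 1)
    trees <- lapply(seq_len(k), function(i) randomRootedTopology(n, brlenMean = 0.15))
    d <- sdagFromTopologies(trees)
    aln <- simulateJCAlignment(trees[[1]], sample(1:3, 1))
    keys <- sdagEdges(d)$key
    pick <- keys[sample(length(keys), min(4L, length(keys)))]
    for (e in pick) {
      diff <- abs(gpLikelihood(d, e, aln) - gpLikelihoodBruteforce(d, e, aln))
      maxdiff <- max(maxdiff, diff)
    }
  }
  expect_lt(maxdiff, 1e-9)
})

test_that("two trees through an edge at one site give the log mean", {
  trees <- unionPairTrees(TRUE)
  d <- sdagFromTopologies(trees, taxa7)
  aln1 <- simulateJCAlignment(trees[[1]], 1, seed = 4)
  e2 <- paste("0001000|0000111", "right", "0000100|0000011")
  Te <- sdagsearch:::.treesThroughEdge(d, e2, 100)
  expect_equal(length(Te), 2L)
  hand <- log(mean(exp(vapply(Te, treeLogLikelihood, 0, aln = aln1))))
  expect_equal(gpLikelihood(d, e2, aln1), hand, tolerance = 1e-10)
})

test_that("the composite and true marginal likelihoods coincide only when
           they must", {
  trees <- unionPairTrees(TRUE)
  d <- sdagFromTopologies(trees, taxa7)
  aln1 <- simulateJCAlignment(trees[[1]], 1, seed = 4)
  alnK <- simulateJCAlignment(trees[[1]], 6, seed = 4)
  keys <- sdagEdges(d)$key
  multi <- keys[vapply(keys, function(e) countTreesThroughEdge(d, e) > 1, TRUE)]
  ## K = 1: equal
  for (e in keys[seq(1, length(keys), 4)])
    expect_equal(gpLikelihoodBruteforce(d, e, aln1),
                 trueMarginalBruteforce(d, e, aln1), tolerance = 1e-9)
  ## |Te| = 1: equal at any K (every edge of a single-topology sDAG)
  d1 <- sdagFromTopologies(trees[[1]])
  single <- sdagEdges(d1)$key[4]
  expect_equal(gpLikelihoodBruteforce(d1, single, alnK),
               trueMarginalBruteforce(d1, single, alnK), tolerance = 1e-10)
  ## K >= 2 with unequal tree likelihoods: strictly different
  difs <- vapply(multi, function(e)
    abs(gpLikelihoodBruteforce(d, e, alnK) - trueMarginalBruteforce(d, e, alnK)), 0)
  expect_true(any(difs > 1e-8))
})

test_that("per-site averaging stays within the per-tree likelihood envelope", {
  trees <- unionPairTrees(TRUE)
  d <- sdagFromTopologies(trees, taxa7)
  aln <- simulateJCAlignment(trees[[1]], 5, seed = 9)
  caln <- sdagsearch:::.compressAlignment(aln, taxa7)
  keys <- sdagEdges(d)$key
  for (e in keys[seq(1, length(keys), 5)]) {
    Te <- sdagsearch:::.treesThroughEdge(d, e, 100)
    siteLL <- vapply(Te, sdagsearch:::.treeSiteLogLik, numeric(caln$nPatterns),
                     caln = caln)
    siteLL <- matrix(siteLL, nrow = caln$nPatterns)
    lo <- sum(apply(siteLL, 1, min) * caln$weights)
    hi <- sum(apply(siteLL, 1, max) * caln$weights)
    g <- gpLikelihood(d, e, aln)
    expect_gte(g, lo - 1e-9)
    expect_lte(g, hi + 1e-9)
  }
})

test_that("GP branch-length optimization matches a grid search", {
  set.seed(81)
  trees <- list(parseNewick("(0:0.1,(1:0.1,(2:0.1,(3:0.1,4:0.1):0.1):0.1):0.1);", taxa5),
                parseNewick("(1:0.1,(0:0.1,((2:0.1,3:0.1):0.1,4:0.1):0.1):0.1);", taxa5))
  d <- completeEdges(sdagFromTopologies(trees, taxa5))$sdag
  aln <- simulateJCAlignment(trees[[1]], 100, seed = 82)
  newKeys <- sdagEdges(d)$key[is.na(sdagEdges(d)$length)]
  expect_equal(length(newKeys), 2L)
  dopt <- gpOptimizeNewEdges(d, newKeys, aln)
  for (e in newKeys) {
    r <- match(e, sdagEdges(dopt)$key)
    f <- function(v) {
      dd <- dopt
      dd@edges$length[r] <- v
      gpLikelihood(dd, e, aln)
    }
    grid <- seq(1e-3, 2, by = 1e-3)
    best <- grid[which.max(vapply(grid, f, 0))]
    expect_equal(dopt@edges$length[r], best, tolerance = 5e-3)
  }
  ## single-topology sDAG: GP optimization equals single-tree optimization
  phy <- trees[[1]]
  d1 <- sdagFromTopologies(phy)
  r <- 6L
  e <- sdagEdges(d1)$key[r]
  d1@edges$length[r] <- NA
  dfit <- gpOptimizeNewEdges(d1, e, aln)
  f1 <- function(v) {
    dd <- d1; dd@edges$length[r] <- v
    treeLogLikelihood(enumerateTopologies(dd)[[1]], aln)
  }
  grid <- seq(1e-3, 2, by = 1e-3)
  expect_equal(dfit@edges$length[r], grid[which.max(vapply(grid, f1, 0))],
               tolerance = 5e-3)
})

test_that("the GP search runs deterministically and grows monotonically", {
  trees <- choicePairTrees()
  aln <- simulateJCAlignment(trees[[1]], 60, seed = 4)
  res <- gpSearch(trees, aln, maxIterations = 3)
  expect_equal(nrow(res$trace), 3L)
  expect_true(all(diff(res$trace$nTopologies) >= 0))
  expect_true(all(diff(res$trace$nEdges) >= 0))
  res2 <- gpSearch(trees, aln, maxIterations = 3)
  expect_identical(res$trace, res2$trace)
  res0 <- gpSearch(trees, aln, maxIterations = 5, likelihoodThreshold = Inf)
  expect_equal(nrow(res0$trace), 0L)
})
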