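## shared fixture: the union-pair sDAG with the worked probability assignment
## (0.4 on the {{0,1},...} root split, 0.3 on the {{4},{5,6}} resolution)
distFixture <- function() {
  d <- sdagFromTopologies(unionPairTrees(), taxa7)
  rho <- sdagsearch:::.rhoKey(7)
  rootSlot <- paste(rho, "right")
  pr <- list()
  pr[[rootSlot]] <- stats::setNames(c(0.4, 0.6), c(
    paste(rho, "right", "1100000|0011111"),
    paste(rho, "right", "1000000|0111111")))
  slot456 <- paste("0001000|0000111", "right")
  pr[[slot456]] <- stats::setNames(c(0.3, 0.7), c(
    paste("0001000|0000111", "right", "0000100|0000011"),
    paste("0001000|0000111", "right", "0000101|0000010")))
  list(d = d, probs = edgeProbabilities(d, pr), rootSlot = rootSlot)
}

test_that("the worked topology probability is the product of edge choices", {
  fx <- distFixture()
  tau <- parseNewick("((0,1),(2,(3,(4,(5,6)))));", taxa7)
  expect_equal(topologyProbability(fx$d, fx$probs, tau), 0.4 * 0.3,
               tolerance = 1e-14)
  ## the four topologies form a normalized distribution
  tot <- sum(vapply(enumerateTopologies(fx$d), function(tp)
    topologyProbability(fx$d, fx$probs, tp), 0))
  expect_equal(tot, 1, tolerance = 1e-12)
  expect_error(topologyProbability(fx$d, fx$probs,
                                   parseNewick("((0,2),(1,(3,(4,(5,6)))));", taxa7)),
               "not contained")
  d1 <- sdagFromTopologies(unionPairTrees()[[1]])
  expect_equal(topologyProbability(d1, edgeProbabilities(d1),
                                   unionPairTrees()[[1]]), 1)
})

test_that("probability vectors must be proper distributions", {
  fx <- distFixture()
  badKeys <- names(fx$probs[[fx$rootSlot]])
  expect_error(edgeProbabilities(fx$d, stats::setNames(
    list(stats::setNames(c(0.5, 0.6), badKeys)), fx$rootSlot)), "sum to")
  expect_error(edgeProbabilities(fx$d, stats::setNames(
    list(stats::setNames(c(-0.1, 1.1), badKeys)), fx$rootSlot)), "negative")
})

test_that("fitting recovers normalized frequency counts", {
  fx <- distFixture()
  trees <- unionPairTrees()
  fit <- fitEdgeProbabilities(fx$d, c(rep(trees[1], 3), trees[2]))
  e0 <- paste(sdagsearch:::.rhoKey(7), "right", "1000000|0111111")
  expect_equal(unname(fit[[fx$rootSlot]][e0]), 0.75)
  ## a single-topology sample gives degenerate vectors
  fit1 <- fitEdgeProbabilities(fx$d, trees[1])
  for (slot in names(fit1))
    expect_true(all(fit1[[slot]] %in% c(0, 1)))
  expect_error(fitEdgeProbabilities(fx$d, list()), "empty")
  ## refit on an i.i.d. sample recovers the generating probabilities
  samp <- sampleTopologies(fx$d, fx$probs, 10000, seed = 77)
  refit <- fitEdgeProbabilities(fx$d, samp)
  maxerr <- max(vapply(names(fx$probs), function(s)
    max(abs(fx$probs[[s]] - refit[[s]])), 0))
  expect_lt(maxerr, 0.03)
  ## exact expectation over the enumeration reproduces the sample's
  ## per-edge frequencies (topology frequencies need not factorize, but
  ## edge marginals are matched exactly by conditional-frequency fitting)
  tops <- enumerateTopologies(fx$d)
  w <- vapply(tops, function(tp) topologyProbability(fx$d, refit, tp), 0)
  topEdgeKeys <- lapply(tops, function(tp) topologyToEdges(tp, taxa7)$key)
  sampKeys <- lapply(samp, function(tp) topologyToEdges(tp, taxa7)$key)
  for (e in sdagEdges(fx$d)$key) {
    fitted <- sum(w[vapply(topEdgeKeys, function(k) e %in% k, TRUE)])
    emp <- mean(vapply(sampKeys, function(k) e %in% k, TRUE))
    expect_equal(fitted, emp, tolerance = 1e-9)
  }
})

test_that("the clade-conditional predicate distinguishes CCDs from sDAG
           distributions", {
  x3 <- parseNewick("(0,(1,(2,(3,4))));", taxa5)
  x4 <- parseNewick("(1,(0,((2,3),4)));", taxa5)
  d <- completeEdges(sdagFromTopologies(list(x3, x4), taxa5))$sdag
  expect_true(isCladeConditional(d, edgeProbabilities(d)))
  ## give the two parents of clade {2,3,4} different vectors
  idx <- sdagsearch:::.sdagIndex(d)
  slots <- names(idx$childRows)
  s234 <- slots[vapply(slots, function(s) {
    p <- strsplit(s, " ", fixed = TRUE)[[1]]
    sdagsearch:::.sideKey(p[1], p[2]) == "00111"
  }, TRUE)]
  expect_gte(length(s234), 2L)
  pr <- list()
  ks <- sdagEdges(d)$key[idx$childRows[[s234[1]]]]
  pr[[s234[1]]] <- stats::setNames(c(0.9, rep(0.1 / (length(ks) - 1),
                                              length(ks) - 1)), ks)
  expect_false(isCladeConditional(d, edgeProbabilities(d, pr)))
})

test_that("credible sets are the minimal prefix at the requested level", {
  x <- lapply(allRootedTopologies(taxa4)[1:4], parseNewick, taxa = taxa4)
  pt <- posteriorTable(x, c(0.5, 0.3, 0.15, 0.05), taxa4)
  cs <- credibleSet(pt, 0.95)
  expect_equal(nrow(cs), 3L)
  expect_equal(sum(cs$density), 0.95)
  ## minimality: dropping the lowest-density member falls below the level
  expect_lt(sum(cs$density) - min(cs$density), 0.95)
  expect_equal(nrow(credibleSet(posteriorTable(x[1], 1), 0.95)), 1L)
  expect_equal(nrow(credibleSet(posteriorTable(x[1:2], c(0.5, 0.5)), 0.6)), 2L)
  err <- expect_error(credibleSet(posteriorTable(x[1], 0.5), 0.95), "shortfall")
})

test_that("coverage sums the density of contained topologies", {
  x3 <- parseNewick("(0,(1,(2,(3,4))));", taxa5)
  x4 <- parseNewick("(1,(0,((2,3),4)));", taxa5)
  d <- sdagFromTopologies(list(x3, x4), taxa5)
  outside <- parseNewick("((0,2),(1,(3,4)));", taxa5)
  pt <- posteriorTable(list(x3, outside), c(0.12, 0.5), taxa5)
  expect_equal(posteriorCoverage(d, pt), 0.12)
  full <- posteriorTable(list(x3, x4), c(0.6, 0.3), taxa5)
  expect_equal(posteriorCoverage(d, full), 0.9)
  none <- posteriorTable(list(outside), 0.5, taxa5)
  expect_equal(posteriorCoverage(d, none), 0)
})

test_that("subsplit credibility counts internal subsplits only", {
  x3 <- parseNewick("(0,(1,(2,(3,4))));", taxa5)
  x4 <- parseNewick("(1,(0,((2,3),4)));", taxa5)
  d <- sdagFromTopologies(list(x3, x4), taxa5)
  sc <- subsplitCredibility(d, list(x3, x4))
  expect_equal(unname(sc["foundFraction"]), 1)
  expect_equal(unname(sc["precision"]), 1)
  d1 <- sdagFromTopologies(x3)
  sc1 <- subsplitCredibility(d1, list(x3, x4))
  expect_equal(unname(sc1["precision"]), 1)
  expect_lt(sc1["foundFraction"], 1)
  ## one non-credible subsplit among k drops precision to (k-1)/k
  extra <- parseNewick("(0,(1,((2,4),3)));", taxa5)
  dplus <- sdagFromTopologies(list(x3, extra), taxa5)
  k <- length(internalSubsplits(dplus))
  credOnly <- subsplitCredibility(dplus, list(x3))
  nonCred <- length(setdiff(internalSubsplits(dplus),
                            internalSubsplits(sdagFromTopologies(x3))))
  expect_equal(unname(credOnly["precision"]), (k - nonCred) / k)
})

test_that("posterior tables read from TSV and match by subsplit identity", {
  x1 <- parseNewick("((0,1),(2,(3,4)));", taxa5)
  path <- tempfile(fileext = ".tsv")
  ## two spellings of the same topology are merged on read
  writeLines(c("((0,1),(2,(3,4)));\t0.4",
               "((2,(4,3)),(1,0));\t0.25",
               "((0,1),((2,3),4));\t0.2"), path)
  pt <- readPosteriorTable(path)
  expect_equal(nrow(pt), 2L)
  expect_equal(pt$density[pt$newick == topoKey(x1)], 0.65)
  bad <- tempfile()
  writeLines("((0,1),(2,(3,4)));\t1.5", bad)
  expect_error(readPosteriorTable(bad), "> 1")
})
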