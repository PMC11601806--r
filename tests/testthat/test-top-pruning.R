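## a small fixed scenario shared by several blocks
tpFixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    trees <- choicePairTrees()
    aln <- simulateJCAlignment(trees[[1]], 100, seed = 21)
    cache <<- list(trees = trees, aln = aln,
                   state = initTopPruning(trees, aln, verify = TRUE))
    cache
  }
})

test_that("initialization labels edges by the first tree containing them", {
  fx <- tpFixture()
  st <- fx$state
  d <- tpSdag(st)
  tt0 <- topologyToEdges(fx$trees[[1]], taxa7)
  tt1 <- topologyToEdges(fx$trees[[2]], taxa7)
  ed <- sdagEdges(d)
  ## edges first appearing in tau0 carry tau0's branch lengths
  for (k in tt0$key)
    expect_equal(ed$length[ed$key == k], tt0$length[tt0$key == k])
  for (k in setdiff(tt1$key, tt0$key))
    expect_equal(ed$length[ed$key == k], tt1$length[tt1$key == k])
  ## unordered input is rejected when verification is on
  expect_error(initTopPruning(rev(fx$trees), fx$aln, verify = TRUE),
               "not ordered")
  expect_error(initTopPruning(list(), fx$aln), "at least one")
})

test_that("single-tree choice maps reproduce the tree from every edge", {
  fx <- tpFixture()
  st1 <- initTopPruning(fx$trees[1], fx$aln)
  want <- writeNewick(fx$trees[[1]])
  for (e in sdagEdges(tpSdag(st1))$key)
    expect_equal(writeNewick(bestKnownTree(st1, e)), want)
})

test_that("best known trees split at the described subsplit boundary", {
  fx <- tpFixture()
  st <- fx$state
  tt0 <- topologyToEdges(fx$trees[[1]], taxa7)
  tt1 <- topologyToEdges(fx$trees[[2]], taxa7)
  key0 <- topoKey(fx$trees[[1]])
  ## tau0-labeled edges return tau0
  for (e in tt0$key)
    expect_equal(topoKey(bestKnownTree(st, e)), key0)
  ## tau1-only edges: the mixed topology tau2 above {{1},{2,3,4,5}}
  ## (tau1's rootward structure with tau0's resolution of {3,4,5}) and
  ## tau3 below (tau0's rootward structure with tau1's resolution)
  tau2 <- topoKey(parseNewick("((0,(1,(2,(3,(4,5))))),6);", taxa7))
  tau3 <- topoKey(parseNewick("(0,((1,(2,((3,4),5))),6));", taxa7))
  boundary <- "0100000|0011110"  # {{1},{2,3,4,5}}
  boundarySize <- sum(sdagsearch:::.keyBits(sdagsearch:::.subsplitUnion(boundary)))
  for (e in setdiff(tt1$key, tt0$key)) {
    got <- topoKey(bestKnownTree(st, e))
    parts <- strsplit(e, " ", fixed = TRUE)[[1]]
    parentUnion <- sum(sdagsearch:::.keyBits(sdagsearch:::.subsplitUnion(parts[1])))
    if (parentUnion > boundarySize) expect_equal(got, tau2)
    else expect_equal(got, tau3)
  }
  ## every best known tree contains its defining edge and lies in the sDAG
  for (e in sdagEdges(tpSdag(st))$key) {
    bk <- bestKnownTree(st, e)
    expect_true(e %in% topologyToEdges(bk, taxa7)$key)
    expect_true(containsTopology(tpSdag(st), bk))
  }
})

test_that("argmax extension picks the likelihood-maximizing slot candidates", {
  trees <- list(parseNewick("(0:0.1,(1:0.1,(2:0.1,(3:0.1,4:0.1):0.1):0.1):0.1);", taxa5),
                parseNewick("(1:0.1,(0:0.1,((2:0.1,3:0.1):0.1,4:0.1):0.1):0.1);", taxa5))
  aln <- simulateJCAlignment(trees[[1]], 60, seed = 13)
  st <- initTopPruning(trees, aln)
  d <- tpSdag(st); choice <- tpChoiceMap(st)
  ## the two completion edges received choices
  base <- sdagFromTopologies(trees, taxa5)
  compKeys <- setdiff(sdagEdges(d)$key, sdagEdges(base)$key)
  expect_equal(length(compKeys), 2L)
  for (e in compKeys) {
    expect_false(anyNA(unlist(choice[e, c("parentEdge", "siblingEdge")])))
    ## exhaustive check: selected best known tree is likelihood-maximal over
    ## all slot-candidate combinations
    idx <- sdagsearch:::.sdagIndex(d)
    caln <- sdagsearch:::.compressAlignment(aln, taxa5)
    slots <- c("parentEdge", "siblingEdge", "leftChildEdge", "rightChildEdge")
    cands <- lapply(slots, function(sl) {
      v <- sdagsearch:::.slotCandidates(d, idx, e, sl)
      if (!length(v)) NA_character_ else v
    })
    combos <- expand.grid(cands, stringsAsFactors = FALSE)
    lls <- vapply(seq_len(nrow(combos)), function(i) {
      ch <- choice
      for (j in seq_along(slots))
        if (!is.na(combos[i, j])) ch[e, slots[j]] <- combos[i, j]
      sdagsearch:::.bktLogLik(d, ch, e, caln)
    }, 0)
    expect_equal(sdagsearch:::.bktLogLik(d, choice, e, caln), max(lls),
                 tolerance = 1e-9)
  }
  ## repeat call with no new edges leaves the state unchanged
  st2 <- extendArgmax(st, character())
  expect_identical(tpChoiceMap(st2), choice)
  expect_identical(sdagEdges(tpSdag(st2)), sdagEdges(d))
})

test_that("the top-pruning likelihood matches direct single-tree evaluation", {
  phy <- parseNewick("((0:0.12,1:0.08):0.1,(2:0.15,3:0.2):0.07);", taxa4)
  aln <- simulateJCAlignment(phy, 200, seed = 31)
  st <- initTopPruning(list(phy), aln)
  pp <- candidateNNIs(tpSdag(st))
  cherry <- pp[pp$source == paste("1100|0011", "left", "1000|0100"), ]
  expect_equal(nrow(cherry), 2L)
  for (i in 1:2) {
    p <- as.list(cherry[i, ])
    ll <- tpLikelihood(st, p)
    ev <- sdagsearch:::.tpEvalProposal(st, p)
    bk <- sdagsearch:::.bestKnownTreeKeys(ev$sdag, ev$choice, p$central)
    ed <- sdagEdges(ev$sdag)
    ed <- ed[match(bk, ed$key), ]
    ## independent grid optimization of the central length on that topology
    f <- function(v) {
      ed$length[ed$key == p$central] <- v
      treeLogLikelihood(sdagsearch:::.edgeSetToPhylo(ed, taxa4), aln)
    }
    grid <- seq(1e-6, 1, length.out = 400)
    expect_equal(ll, max(vapply(grid, f, 0)), tolerance = 0.01)
    ## upper bound: tp likelihood never exceeds the max over Te
    Te <- sdagsearch:::.treesThroughEdge(ev$sdag, p$central, 100)
    expect_lte(ll, max(vapply(Te, treeLogLikelihood, 0, aln = aln)) + 1e-9)
  }
})

test_that("the search recovers the generating topology and grows monotonically", {
  gen <- parseNewick("((0:0.1,1:0.15):0.08,(2:0.12,3:0.2):0.09);", taxa4)
  aln <- simulateJCAlignment(gen, 500, seed = 41)
  start <- parseNewick("(((0:0.1,1:0.1):0.1,2:0.1):0.1,3:0.1);", taxa4)
  fit <- optimizeBranchLengths(function(x) {
    s <- start; s$edge.length <- x
    treeLogLikelihood(s, aln)
  }, start$edge.length)
  start$edge.length <- as.numeric(fit)
  res <- tpSearch(list(start), aln, maxIterations = 30)
  expect_true(containsTopology(res$sdag, gen))
  tr <- res$trace
  expect_true(all(diff(tr$nTopologies) >= 0))
  expect_true(all(diff(tr$nNodes) >= 0))
  expect_true(all(diff(tr$nEdges) >= 0))
  ## an infinite threshold performs no iterations
  res0 <- tpSearch(list(start), aln, maxIterations = 5,
                   likelihoodThreshold = Inf)
  expect_equal(nrow(res0$trace), 0L)
  expect_identical(sdagEdges(res0$sdag)$key,
                   sdagEdges(tpSdag(initTopPruning(list(start), aln)))$key)
})

test_that("each applied proposal had the maximum cached likelihood at pop time", {
  fx <- tpFixture()
  res <- tpSearch(fx$trees, fx$aln, maxIterations = 4)
  tr <- res$trace
  expect_gt(nrow(tr), 0L)
  ## the trace records cached values; re-running is deterministic
  res2 <- tpSearch(fx$trees, fx$aln, maxIterations = 4)
  expect_identical(res$trace, res2$trace)
})
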