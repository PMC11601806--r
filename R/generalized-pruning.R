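## Generalized pruning: the per-edge topology-marginal composite likelihood
## over the trees of an sDAG containing a given edge, computed by a two-pass
## PLV dynamic program, with brute-force enumeration oracles and the 8-step
## GP search.

## ---- tree counting through an edge ---------------------------------------

## per-node below counts and per-edge above counts
.gpCounts <- function(d, idx = .sdagIndex(d)) {
  below <- .sdagBelowCounts(d, idx)
  ed <- d@edges
  usize <- idx$usize[ed$parent]
  above <- stats::setNames(numeric(nrow(ed)), ed$key)
  ## process edges with larger parent unions first (parents above children)
  for (r in order(-usize)) {
    t <- ed$parent[r]
    if (idx$isRho[[t]]) { above[r] <- 1; next }
    sib <- .otherSide(ed$which[r])
    sibRows <- idx$childRows[[paste(t, sib)]]
    sibFactor <- if (is.null(sibRows)) 1 else sum(below[ed$child[sibRows]])
    parentRows <- idx$parentRows[[t]]
    above[r] <- sum(above[parentRows]) * sibFactor
  }
  list(below = below, above = above)
}

#' Number of trees of an sDAG containing a given edge
#'
#' `|Te|`, the denominator of the uniform-prior conditional `p(tau | e)`, by
#' the product of the subtree-count below the edge's child and the
#' rootward-completion count above the edge.
#'
#' @param d a [SubsplitDAG-class].
#' @param e an edge key (`"parent which child"`).
#' @return numeric count.
#' @export
countTreesThroughEdge <- function(d, e) {
  r <- match(e, d@edges$key)
  if (is.na(r)) stop("edge not in sDAG: ", e)
  cnt <- .gpCounts(d)
  unname(cnt$above[r] * cnt$below[d@edges$child[r]])
}

## ---- the PLV dynamic program ---------------------------------------------

## Scaled per-pattern vector sets: value = list(mat = 4 x P, ls = log-scale
## per pattern). Effective value is mat * exp(ls) columnwise.
.plvRescale <- function(mat, ls) {
  mx <- apply(mat, 2L, max)
  pos <- mx > 0 & is.finite(mx)
  mat[, pos] <- mat[, pos, drop = FALSE] / rep(mx[pos], each = 4L)
  ls[pos] <- ls[pos] + log(mx[pos])
  list(mat = mat, ls = ls)
}

## sum of scaled vector sets
.plvSum <- function(items) {
  if (length(items) == 1L) return(items[[1L]])
  lsmax <- items[[1L]]$ls
  for (it in items[-1L]) lsmax <- pmax(lsmax, it$ls)
  P <- length(lsmax)
  acc <- matrix(0, 4L, P)
  for (it in items) acc <- acc + it$mat * rep(exp(it$ls - lsmax), each = 4L)
  .plvRescale(acc, lsmax)
}

## leafward pass: p(node) and phat(node, clade) for every node/clade;
## phat(t, w)_x = sum over edges (t,w)->c of [P(len) p(c)]_x
.gpLeafward <- function(d, caln, idx = .sdagIndex(d)) {
  ed <- d@edges
  if (anyNA(ed$length[!idx$isRho[ed$parent]]))
    stop("sDAG has unset (sentinel) branch lengths")
  P <- caln$nPatterns
  ones <- list(mat = matrix(1, 4L, P), ls = numeric(P))
  empty <- .emptyKey(length(d@taxa))
  pvec <- new.env(parent = emptyenv(), hash = TRUE)
  phat <- new.env(parent = emptyenv(), hash = TRUE)
  for (nd in idx$nodesAsc) {
    if (idx$isLeaf[[nd]]) {
      taxon <- d@taxa[.keyBits(idx$right[[nd]])]
      pvec[[nd]] <- list(mat = caln$partials[[taxon]], ls = numeric(P))
      next
    }
    if (idx$isRho[[nd]]) next
    sides <- list()
    for (w in c("left", "right")) {
      if (idx[[w]][[nd]] == empty) { phat[[paste(nd, w)]] <- ones; next }
      rows <- idx$childRows[[paste(nd, w)]]
      items <- lapply(rows, function(r) {
        ch <- pvec[[ed$child[r]]]
        list(mat = jcTransitionMatrix(ed$length[r]) %*% ch$mat, ls = ch$ls)
      })
      ph <- .plvSum(items)
      phat[[paste(nd, w)]] <- ph
      sides[[length(sides) + 1L]] <- ph
    }
    stopifnot(length(sides) == 2L)
    pvec[[nd]] <- .plvRescale(sides[[1L]]$mat * sides[[2L]]$mat,
                              sides[[1L]]$ls + sides[[2L]]$ls)
  }
  list(pvec = pvec, phat = phat, ones = ones)
}

## rootward pass: r(t) per node (data above t given state at t, summed over
## rootward completions, root prior 1/4 folded in at root splits)
.gpRootward <- function(d, lw, idx = .sdagIndex(d)) {
  ed <- d@edges
  P <- length(lw$ones$ls)
  rvec <- new.env(parent = emptyenv(), hash = TRUE)
  for (nd in rev(idx$nodesAsc)) {
    if (idx$isRho[[nd]] || idx$isLeaf[[nd]]) next
    if (idx$unions[[nd]] == .fullKey(length(d@taxa))) {
      rvec[[nd]] <- list(mat = matrix(0.25, 4L, P), ls = numeric(P))
      next
    }
    items <- list()
    for (r in idx$parentRows[[nd]]) {
      t <- ed$parent[r]
      ab <- .gpAbove(d, r, lw, rvec)
      items[[length(items) + 1L]] <-
        list(mat = t(jcTransitionMatrix(ed$length[r])) %*% ab$mat, ls = ab$ls)
    }
    rvec[[nd]] <- .plvSum(items)
  }
  rvec
}

## above(e) for edge row r: r(t) * phat(t, sibling clade of e)
.gpAbove <- function(d, r, lw, rvec) {
  ed <- d@edges
  t <- ed$parent[r]
  rt <- rvec[[t]]
  sib <- lw$phat[[paste(t, .otherSide(ed$which[r]))]]
  if (is.null(sib)) sib <- lw$ones
  .plvRescale(rt$mat * sib$mat, rt$ls + sib$ls)
}

#' Generalized pruning per-edge composite marginal log likelihood
#'
#' For edge `e` of the sDAG, computes
#' `sum_j log[ (1/|Te|) * sum_{tau in Te} p(Y_j | tau) ]`,
#' where `Te` is the set of trees of the sDAG containing `e`, via the shared
#' two-pass PLV dynamic program (leafward clade-sum vectors, rootward vectors,
#' stationary 1/4 root frequencies, uniform prior over `Te`).
#'
#' @param d a [SubsplitDAG-class] with all non-rho branch lengths assigned.
#' @param e an edge key present in `d`, or a vector of them.
#' @param aln an alignment (see [treeLogLikelihood()]).
#' @return numeric log composite likelihood, one value per requested edge.
#' @export
gpLikelihood <- function(d, e, aln) {
  rows <- match(e, d@edges$key)
  if (anyNA(rows)) stop("edge not in sDAG: ", e[which(is.na(rows))[1L]])
  caln <- if (is.list(aln) && !is.null(aln$partials)) aln
          else .compressAlignment(aln, d@taxa)
  eng <- .gpEngine(d, caln)
  vapply(rows, eng, 0)
}

## build the DP caches once; returns function(edge row) -> gp log likelihood
.gpEngine <- function(d, caln) {
  idx <- .sdagIndex(d)
  lw <- .gpLeafward(d, caln, idx)
  rvec <- .gpRootward(d, lw, idx)
  cnt <- .gpCounts(d, idx)
  ed <- d@edges
  function(r) {
    if (.isRhoKey(ed$parent[r])) {
      ## rho edge: Te = all trees through the root split child
      ch <- lw$pvec[[ed$child[r]]]
      sj <- log(colSums(ch$mat * 0.25)) + ch$ls
      nTe <- cnt$below[ed$child[r]]
      return(sum((sj - log(nTe)) * caln$weights))
    }
    ab <- .gpAbove(d, r, lw, rvec)
    ch <- lw$pvec[[ed$child[r]]]
    contrib <- jcTransitionMatrix(ed$length[r]) %*% ch$mat
    sj <- log(colSums(ab$mat * contrib)) + ab$ls + ch$ls
    nTe <- cnt$above[r] * cnt$below[ed$child[r]]
    sum((sj - log(nTe)) * caln$weights)
  }
}

## Constant-time line-search objective for one (non-rho) edge: the edge's
## above vector, child vector and |Te| do not depend on its own length, so a
## Brent search over that length can reuse the caches built at the current
## lengths of all other edges.
.gpEdgeObjective <- function(d, caln, r, idx, lw, rvec, cnt) {
  ed <- d@edges
  ab <- .gpAbove(d, r, lw, rvec)
  ch <- lw$pvec[[ed$child[r]]]
  nTe <- cnt$above[r] * cnt$below[ed$child[r]]
  base <- ab$ls + ch$ls - log(nTe)
  function(v) {
    contrib <- jcTransitionMatrix(v) %*% ch$mat
    sum((log(colSums(ab$mat * contrib)) + base) * caln$weights)
  }
}

## ---- enumeration oracles -------------------------------------------------

## trees of d containing edge e, as phylo objects with the sDAG lengths
.treesThroughEdge <- function(d, e, cap = 1e5) {
  nTe <- countTreesThroughEdge(d, e)
  if (nTe > cap) stop("|Te| = ", nTe, " exceeds the enumeration cap ", cap)
  tops <- enumerateTopologies(d, cap = cap)
  keep <- vapply(tops, function(tp) e %in% .phyloToTtree(tp, d@taxa)$key, TRUE)
  tops[keep]
}

#' Brute-force evaluation of the GP composite likelihood
#'
#' Enumerates `Te`, computes each tree's per-site likelihoods, averages per
#' site, and sums the per-site logs. Independent of the dynamic program; used
#' as its oracle.
#'
#' @inheritParams gpLikelihood
#' @param cap enumeration guard on `|Te|`.
#' @export
gpLikelihoodBruteforce <- function(d, e, aln, cap = 1e5) {
  trees <- .treesThroughEdge(d, e, cap)
  caln <- .compressAlignment(aln, d@taxa)
  siteLL <- vapply(trees, .treeSiteLogLik, numeric(caln$nPatterns), caln = caln)
  siteLL <- matrix(siteLL, nrow = caln$nPatterns)
  mx <- apply(siteLL, 1L, max)
  avg <- mx + log(rowMeans(exp(siteLL - mx)))
  sum(avg * caln$weights)
}

#' Brute-force true (non-composite) marginal likelihood of an edge
#'
#' `log sum_{tau in Te} p(tau|e) prod_j p(Y_j|tau)`: the whole-alignment tree
#' average, as opposed to the GP composite's per-site average. The two
#' coincide when `|Te| = 1` or at a single site, and differ otherwise.
#'
#' @inheritParams gpLikelihoodBruteforce
#' @export
trueMarginalBruteforce <- function(d, e, aln, cap = 1e5) {
  trees <- .treesThroughEdge(d, e, cap)
  caln <- .compressAlignment(aln, d@taxa)
  lls <- vapply(trees, function(tp) sum(.treeSiteLogLik(tp, caln) * caln$weights), 0)
  mx <- max(lls)
  mx + log(mean(exp(lls - mx)))
}

## ---- branch-length optimization and search -------------------------------

#' Optimize new-edge branch lengths under the GP objective
#'
#' Coordinate ascent over the given edges (canonical order), each coordinate
#' maximizing the GP composite likelihood of its own edge with Brent's method;
#' lengths of all other edges are left unaltered.
#'
#' @param d a [SubsplitDAG-class].
#' @param newEdges character vector of edge keys to optimize; NA-sentinel
#'   lengths are initialized from `init` before optimization.
#' @param aln an alignment.
#' @param init initial length for sentinel edges.
#' @param config see [sdagConfig()].
#' @return the sDAG with optimized lengths on `newEdges`.
#' @export
gpOptimizeNewEdges <- function(d, newEdges, aln, init = NULL,
                               config = sdagConfig()) {
  if (!length(newEdges)) return(d)
  rows <- match(newEdges, d@edges$key)
  if (anyNA(rows)) stop("edge not in sDAG: ", newEdges[which(is.na(rows))[1L]])
  if (is.null(init)) init <- config$newEdgeInit
  rhoRows <- vapply(d@edges$parent[rows], .isRhoKey, TRUE)
  d@edges$length[rows[rhoRows]] <- 0
  rows <- rows[!rhoRows]
  if (!length(rows)) return(d)
  d@edges$length[rows][is.na(d@edges$length[rows])] <- init
  caln <- .compressAlignment(aln, d@taxa)
  ord <- order(.edgeSortKey(d@edges$parent[rows], d@edges$which[rows],
                            d@edges$child[rows]), method = "radix")
  rows <- rows[ord]
  for (sweep in seq_len(config$maxSweeps)) {
    maxDelta <- 0
    for (r in rows) {
      ## rebuild the caches at the current lengths, then line-search this
      ## edge's length (its own caches are invariant along the line)
      idx <- .sdagIndex(d)
      lw <- .gpLeafward(d, caln, idx)
      rvec <- .gpRootward(d, lw, idx)
      cnt <- .gpCounts(d, idx)
      fi <- .gpEdgeObjective(d, caln, r, idx, lw, rvec, cnt)
      opt <- stats::optimize(fi, lower = config$brlenLower,
                             upper = config$brlenUpper, maximum = TRUE,
                             tol = config$brlenTol)
      cand <- c(opt$maximum, d@edges$length[r], config$brlenLower)
      vals <- c(opt$objective, fi(d@edges$length[r]), fi(config$brlenLower))
      best <- which.max(vals)
      maxDelta <- max(maxDelta, abs(cand[best] - d@edges$length[r]))
      d@edges$length[r] <- cand[best]
    }
    if (maxDelta < config$brlenTol) break
  }
  d
}

#' Generalized pruning NNI search
#'
#' Initializes the sDAG from a likelihood-ordered tree list (branch lengths
#' from the first tree containing each edge), completes all compatible edges
#' with GP-optimized lengths, then iterates: rank candidate NNIs by the GP
#' composite likelihood of the central edge in the hypothetical post-NNI sDAG
#' (new-edge lengths optimized), apply the best proposal with
#' around-new-nodes completion, and insert newly enabled proposals without
#' refreshing cached likelihoods of old entries.
#'
#' @param trees list of phylo objects, ordered by decreasing likelihood.
#' @param aln an alignment.
#' @param maxIterations iteration cap.
#' @param likelihoodThreshold stop once the best queued GP likelihood falls
#'   below this (default `-Inf`: run to `maxIterations`).
#' @param initGlobalOpt additionally sweep GP optimization over all initial
#'   edges before searching (off by default).
#' @param config see [sdagConfig()].
#' @param taxa optional taxon universe.
#' @return list with `sdag` (final) and `trace` (data.frame per iteration:
#'   `iteration`, `central`, `gpLogLik`, `nNodes`, `nEdges`, `nTopologies`).
#' @export
gpSearch <- function(trees, aln, maxIterations = 10L,
                     likelihoodThreshold = -Inf, initGlobalOpt = FALSE,
                     config = sdagConfig(), taxa = NULL) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (!length(trees)) stop("need at least one starting tree")
  d <- sdagFromTopologies(trees, taxa)
  caln <- .compressAlignment(aln, d@taxa)
  if (initGlobalOpt)
    d <- gpOptimizeNewEdges(d, d@edges$key, aln, config = config)
  comp <- completeEdges(d)
  d <- comp$sdag
  sentinels <- d@edges$key[is.na(d@edges$length)]
  d <- gpOptimizeNewEdges(d, sentinels, aln, config = config)
  evalProposal <- function(d, p) {
    ap <- applyNNI(d, p, "around_new_nodes")
    d2 <- ap$sdag
    ## initialize new lengths from pre-NNI counterparts where they exist
    rows <- match(ap$newEdges$key, d2@edges$key)
    for (i in seq_along(rows)) {
      from <- ap$newEdges$from[i]
      if (!is.na(from)) {
        fr <- match(from, d@edges$key)
        if (!is.na(fr)) d2@edges$length[rows[i]] <- d@edges$length[fr]
      }
    }
    d2 <- gpOptimizeNewEdges(d2, ap$newEdges$key, aln, config = config)
    list(sdag = d2, gp = .gpEngine(d2, caln)(match(p$central, d2@edges$key)))
  }
  queue <- data.frame()
  addProposals <- function(queue, d) {
    cand <- candidateNNIs(d)
    if (!nrow(cand)) return(queue)
    pairKey <- paste(cand$tPrime, cand$sPrime)
    seen <- if (nrow(queue)) paste(queue$tPrime, queue$sPrime) else character()
    cand <- cand[!(pairKey %in% seen), , drop = FALSE]
    if (!nrow(cand)) return(queue)
    cand$gpLogLik <- vapply(seq_len(nrow(cand)), function(i)
      evalProposal(d, as.list(cand[i, ]))$gp, 0)
    rbind(queue, cand)
  }
  queue <- addProposals(queue, d)
  trace <- data.frame()
  iter <- 0L
  while (iter < maxIterations && nrow(queue)) {
    queue <- queue[order(-queue$gpLogLik,
                         .edgeSortKey(queue$tPrime, queue$centralWhich, queue$sPrime),
                         method = "radix"), , drop = FALSE]
    if (queue$gpLogLik[1L] < likelihoodThreshold) break
    p <- as.list(queue[1L, ])
    queue <- queue[-1L, , drop = FALSE]
    if (!.nniEnlarges(d, p)) next
    res <- evalProposal(d, p)
    d <- res$sdag
    iter <- iter + 1L
    trace <- rbind(trace, data.frame(
      iteration = iter, central = p$central, gpLogLik = res$gp,
      nNodes = length(d@nodes), nEdges = nrow(d@edges),
      nTopologies = countTopologies(d), stringsAsFactors = FALSE))
    queue <- addProposals(queue, d)
  }
  list(sdag = d, trace = trace)
}
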