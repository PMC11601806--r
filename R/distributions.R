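## Probability distributions on sDAG edges, topology probabilities, fitting
## from topology samples, credible sets, and posterior-coverage metrics.

## EdgeProbabilities: a named list keyed by "(node, which)" (the paste of a
## subsplit key and a clade side); each element is a probability vector named
## by the outgoing edge keys.

#' Build or validate an edge-probability assignment
#'
#' An edge-probability assignment gives, for each (subsplit, clade) pair with
#' outdegree >= 1, a probability distribution over its outgoing edges: this
#' turns the sDAG into a normalized distribution over the topologies it
#' contains.
#'
#' @param d a [SubsplitDAG-class].
#' @param probs named list: names `"<subsplitkey> <which>"`, values numeric
#'   probability vectors named by edge keys. Missing (node, clade) pairs get
#'   the uniform distribution over their outgoing edges.
#' @return the completed, validated assignment (class `"edgeProbs"`).
#' @export
edgeProbabilities <- function(d, probs = list()) {
  idx <- .sdagIndex(d)
  out <- list()
  for (slot in names(idx$childRows)) {
    rows <- idx$childRows[[slot]]
    keys <- d@edges$key[rows]
    v <- probs[[slot]]
    if (is.null(v)) {
      v <- stats::setNames(rep(1 / length(keys), length(keys)), keys)
    } else {
      if (!setequal(names(v), keys))
        stop("probability vector at ", slot, " does not match the outgoing edges")
      v <- v[keys]
      if (any(v < 0)) stop("negative probability at ", slot)
      if (abs(sum(v) - 1) > 1e-12)
        stop("probabilities at ", slot, " sum to ", sum(v), ", not 1")
    }
    out[[slot]] <- v
  }
  structure(out, class = "edgeProbs")
}

#' Probability of a topology under an edge-probability assignment
#'
#' The product, over the topology's edges, of each edge's conditional
#' probability; (node, clade) pairs with a single outgoing edge contribute
#' factor 1.
#'
#' @param d a [SubsplitDAG-class].
#' @param probs an assignment from [edgeProbabilities()].
#' @param phy a topology contained in `d`.
#' @return numeric probability.
#' @export
topologyProbability <- function(d, probs, phy) {
  tt <- .phyloToTtree(phy, d@taxa)
  if (!all(tt$key %in% d@edges$key))
    stop("topology is not contained in the sDAG")
  pr <- 1
  for (r in seq_len(nrow(tt))) {
    slot <- paste(tt$parent[r], tt$which[r])
    v <- probs[[slot]]
    if (is.null(v)) stop("no probability vector at ", slot)
    pr <- pr * unname(v[tt$key[r]])
  }
  pr
}

#' Fit edge probabilities from a topology sample
#'
#' For each (parent subsplit, clade), the probability of a child edge is the
#' normalized frequency of that child among the sampled topologies containing
#' the parent subsplit. (node, clade) pairs never visited by the sample get
#' the uniform vector.
#'
#' @param d a [SubsplitDAG-class] containing every sampled topology.
#' @param sample list of phylo objects (repeats allowed).
#' @return an `"edgeProbs"` assignment.
#' @export
fitEdgeProbabilities <- function(d, sample) {
  if (inherits(sample, "phylo")) sample <- list(sample)
  if (!length(sample)) stop("empty topology sample")
  edgeCount <- new.env(parent = emptyenv(), hash = TRUE)
  slotCount <- new.env(parent = emptyenv(), hash = TRUE)
  for (phy in sample) {
    tt <- .phyloToTtree(phy, d@taxa)
    if (!all(tt$key %in% d@edges$key))
      stop("sampled topology not contained in the sDAG")
    for (r in seq_len(nrow(tt))) {
      k <- tt$key[r]
      slot <- paste(tt$parent[r], tt$which[r])
      edgeCount[[k]] <- (edgeCount[[k]] %||% 0) + 1
      slotCount[[slot]] <- (slotCount[[slot]] %||% 0) + 1
    }
  }
  idx <- .sdagIndex(d)
  probs <- list()
  for (slot in names(idx$childRows)) {
    tot <- slotCount[[slot]]
    if (is.null(tot)) next
    keys <- d@edges$key[idx$childRows[[slot]]]
    cnt <- vapply(keys, function(k) edgeCount[[k]] %||% 0, 0)
    probs[[slot]] <- cnt / tot
  }
  edgeProbabilities(d, probs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sample topologies from an sDAG distribution
#'
#' Top-down sampling: starting at rho, choose an outgoing edge at each
#' (node, clade) according to `probs` and recurse.
#'
#' @param d a [SubsplitDAG-class].
#' @param probs an `"edgeProbs"` assignment.
#' @param n number of samples.
#' @param seed optional integer seed.
#' @return a list of phylo objects.
#' @export
sampleTopologies <- function(d, probs, n, seed = NULL) {
  idx <- .sdagIndex(d)
  ed <- d@edges
  .withSeed(seed, {
    lapply(seq_len(n), function(i) {
      rows <- integer()
      walk <- function(node) {
        for (w in c("left", "right")) {
          slot <- paste(node, w)
          v <- probs[[slot]]
          if (is.null(v)) next
          k <- if (length(v) == 1L) names(v) else sample(names(v), 1L, prob = v)
          r <- match(k, ed$key)
          rows <<- c(rows, r)
          if (!.isLeafKey(ed$child[r])) walk(ed$child[r])
        }
      }
      walk(.rhoKey(length(d@taxa)))
      sub <- ed[rows, , drop = FALSE]
      sub$length[is.na(sub$length)] <- 0
      .edgeSetToPhylo(sub, d@taxa, withLengths = FALSE)
    })
  })
}

#' Is an edge-probability assignment clade-conditional?
#'
#' Conditional clade distributions (CCDs) are the special case of sDAG
#' distributions where all (node, clade) pairs sharing the same clade carry
#' identical distributions over the child subsplits. The sDAG is a strict
#' generalization: it may condition on the sister clade as well.
#'
#' @param d a [SubsplitDAG-class].
#' @param probs an `"edgeProbs"` assignment.
#' @param tol numeric comparison tolerance.
#' @return logical.
#' @export
isCladeConditional <- function(d, probs, tol = 1e-12) {
  bySubsplit <- list()
  for (slot in names(probs)) {
    parts <- strsplit(slot, " ", fixed = TRUE)[[1]]
    clade <- .sideKey(parts[1L], parts[2L])
    v <- probs[[slot]]
    childDist <- stats::setNames(as.numeric(v),
      vapply(strsplit(names(v), " ", fixed = TRUE), `[`, "", 3L))
    childDist <- childDist[order(names(childDist), method = "radix")]
    prev <- bySubsplit[[clade]]
    if (is.null(prev)) { bySubsplit[[clade]] <- childDist; next }
    if (!identical(names(prev), names(childDist))) return(FALSE)
    if (max(abs(prev - childDist)) > tol) return(FALSE)
  }
  TRUE
}

## ---- posterior tables and coverage ---------------------------------------

#' Read a topology posterior table
#'
#' Tab-separated file, one row per topology: `newick<TAB>density`. Topologies
#' are canonicalized on read (matching is by subsplit-set identity, not string
#' equality); duplicate topologies have their densities summed.
#'
#' @param path TSV file path.
#' @param taxa optional taxon universe.
#' @return a data.frame with columns `newick` (canonical), `density`, and
#'   attribute `taxa`; densities must total at most 1 (small slack).
#' @export
readPosteriorTable <- function(path, taxa = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 2L)
  if (length(bad)) stop("malformed posterior line ", bad[1L])
  trees <- lapply(fields, function(f) parseNewick(f[1L], taxa))
  if (is.null(taxa)) taxa <- treeTaxa(trees[[1L]])
  dens <- vapply(fields, function(f) as.numeric(f[2L]), 0)
  if (anyNA(dens) || any(dens < 0)) stop("bad density value")
  canon <- vapply(trees, function(tr) {
    tr$edge.length <- NULL
    writeNewick(tr, taxa)
  }, "")
  agg <- tapply(dens, canon, sum)
  out <- data.frame(newick = names(agg), density = as.numeric(agg),
                    stringsAsFactors = FALSE)
  if (sum(out$density) > 1 + 1e-9)
    stop("densities sum to ", sum(out$density), " > 1")
  out <- out[order(-out$density, out$newick, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "taxa") <- taxa
  out
}

#' Build a posterior table in memory
#' @param topologies list of phylo objects.
#' @param densities numeric densities in `[0, 1]` (sum at most 1).
#' @param taxa optional taxon universe.
#' @return a posterior table as from [readPosteriorTable()].
#' @export
posteriorTable <- function(topologies, densities, taxa = NULL) {
  if (inherits(topologies, "phylo")) topologies <- list(topologies)
  if (is.null(taxa)) taxa <- treeTaxa(topologies[[1L]])
  canon <- vapply(topologies, function(tr) {
    tr$edge.length <- NULL
    writeNewick(tr, taxa)
  }, "")
  agg <- tapply(densities, canon, sum)
  out <- data.frame(newick = names(agg), density = as.numeric(agg),
                    stringsAsFactors = FALSE)
  if (sum(out$density) > 1 + 1e-9)
    stop("densities sum to ", sum(out$density), " > 1")
  out <- out[order(-out$density, out$newick, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "taxa") <- taxa
  out
}

#' Credible set of a topology posterior
#'
#' The minimal-size set of topologies whose cumulative density reaches
#' `level`: topologies sorted by density descending (ties by canonical Newick
#' string), shortest prefix with cumulative density >= level.
#'
#' @param post a posterior table.
#' @param level credible level in (0, 1].
#' @return the subset of rows forming the credible set.
#' @export
credibleSet <- function(post, level = 0.95) {
  if (level <= 0 || level > 1) stop("level must be in (0, 1]")
  tot <- sum(post$density)
  if (tot < level)
    stop("total density ", sprintf("%.6g", tot), " is below the requested level ",
         level, " (shortfall ", sprintf("%.6g", level - tot), ")")
  ord <- order(-post$density, post$newick, method = "radix")
  cum <- cumsum(post$density[ord])
  k <- which(cum >= level - 1e-12)[1L]
  out <- post[ord[seq_len(k)], , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "taxa") <- attr(post, "taxa")
  out
}

#' Posterior density covered by an sDAG
#'
#' The total posterior density of the table's topologies contained in the
#' sDAG.
#'
#' @param d a [SubsplitDAG-class].
#' @param post a posterior table on the same taxa.
#' @return numeric in `[0, 1]`.
#' @export
posteriorCoverage <- function(d, post) {
  taxa <- attr(post, "taxa")
  if (!is.null(taxa) && !setequal(taxa, d@taxa))
    stop("posterior table and sDAG are on different taxon sets")
  inDag <- vapply(post$newick, function(nw)
    containsTopology(d, parseNewick(nw, d@taxa)), TRUE)
  sum(post$density[inDag])
}

#' Subsplit credibility of an sDAG
#'
#' A subsplit is credible if it appears in at least one topology of the
#' credible set. Returns the fraction of credible subsplits present in the
#' sDAG (`foundFraction`) and the fraction of the sDAG's subsplits that are
#' credible (`precision`). Leaf subsplits and rho are excluded from both
#' counts.
#'
#' @param d a [SubsplitDAG-class].
#' @param credible a credible set (rows of a posterior table) or a list of
#'   phylo objects.
#' @return named numeric vector `c(foundFraction, precision)`.
#' @export
subsplitCredibility <- function(d, credible) {
  trees <- if (is.data.frame(credible))
    lapply(credible$newick, parseNewick, taxa = d@taxa)
  else if (inherits(credible, "phylo")) list(credible)
  else credible
  if (!length(trees)) stop("empty credible set")
  credSS <- unique(unlist(lapply(trees, function(tr) {
    tt <- .phyloToTtree(tr, d@taxa)
    setdiff(unique(c(tt$parent, tt$child)),
            c(.rhoKey(length(d@taxa)),
              vapply(seq_along(d@taxa), .leafKey, "", n = length(d@taxa))))
  })))
  dagSS <- internalSubsplits(d)
  inter <- length(intersect(credSS, dagSS))
  c(foundFraction = inter / length(credSS), precision = inter / length(dagSS))
}
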