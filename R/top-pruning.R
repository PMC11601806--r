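## Top pruning: choice maps, best-known-tree extraction, the top-pruning
## likelihood of an NNI, and the iterative top-pruning search.

#' Top-pruning search state
#'
#' Bundles the current sDAG, its choice maps (per edge: a rootward
#' parent+sibling selection and a leafward left/right child selection), the
#' ranked NNI queue with cached top-pruning likelihoods, the pattern-compressed
#' alignment, and tunable parameters.
#'
#' @slot sdag the current [SubsplitDAG-class].
#' @slot choice data.frame keyed by edge (rownames): columns `parentEdge`,
#'   `siblingEdge`, `leftChildEdge`, `rightChildEdge` (edge keys or NA where
#'   the respective neighbor does not exist: no rootward pair for edges from
#'   rho, no children for edges into leaves).
#' @slot queue data.frame of pending NNI proposals with cached `tpLogLik`
#'   (cached values are never recomputed in place).
#' @slot caln pattern-compressed alignment (internal representation).
#' @slot config parameter list from [sdagConfig()].
#' @export
setClass("TPState",
         representation(sdag = "SubsplitDAG", choice = "data.frame",
                        queue = "data.frame", caln = "list", config = "list"))

setMethod("show", "TPState", function(object) {
  cat("TPState: ", length(object@sdag@nodes), " nodes, ",
      nrow(object@sdag@edges), " edges, ", nrow(object@queue),
      " queued NNI proposal(s)\n", sep = "")
})

#' @describeIn TPState-class current sDAG.
#' @param state a TPState.
#' @export
tpSdag <- function(state) state@sdag

#' @describeIn TPState-class choice-map table.
#' @export
tpChoiceMap <- function(state) state@choice

#' @describeIn TPState-class pending proposal queue with cached likelihoods.
#' @export
tpQueue <- function(state) state@queue

## empty choice row
.choiceRow <- function() {
  data.frame(parentEdge = NA_character_, siblingEdge = NA_character_,
             leftChildEdge = NA_character_, rightChildEdge = NA_character_,
             stringsAsFactors = FALSE)
}

## choice-map rows for the edges of a single tree (its own neighbors)
.treeChoices <- function(tt) {
  byParentWhich <- stats::setNames(tt$key, paste(tt$parent, tt$which))
  byChild <- stats::setNames(tt$key, tt$child)
  out <- .choiceRow()[rep(1L, nrow(tt)), , drop = FALSE]
  rownames(out) <- tt$key
  for (r in seq_len(nrow(tt))) {
    t <- tt$parent[r]; w <- tt$which[r]; s <- tt$child[r]
    if (!.isRhoKey(t)) {
      out$parentEdge[r] <- unname(byChild[t])
      out$siblingEdge[r] <- unname(byParentWhich[paste(t, .otherSide(w))])
    }
    if (!.isLeafKey(s)) {
      out$leftChildEdge[r] <- unname(byParentWhich[paste(s, "left")])
      out$rightChildEdge[r] <- unname(byParentWhich[paste(s, "right")])
    }
  }
  out
}

## ---- best known tree -----------------------------------------------------

## edge-key set of the best known tree for `edge`, by the deterministic
## recursive closure of the choice maps
.bestKnownTreeKeys <- function(d, choice, edge) {
  if (!(edge %in% rownames(choice))) stop("no choice map for edge ", edge)
  inG <- new.env(parent = emptyenv(), hash = TRUE)
  slotFilled <- new.env(parent = emptyenv(), hash = TRUE) # (node,clade)/child marks
  G <- character()
  addEdge <- function(k) {
    if (!is.null(inG[[k]])) return()
    inG[[k]] <- TRUE
    G <<- c(G, k)
  }
  addEdge(edge)
  maxAdd <- 4L * length(d@taxa) + 8L
  for (iter in seq_len(maxAdd)) {
    grew <- FALSE
    for (e in G) {
      parts <- strsplit(e, " ", fixed = TRUE)[[1]]
      t <- parts[1L]; w <- parts[2L]; s <- parts[3L]
      ch <- choice[e, , drop = FALSE]
      if (is.null(ch) || !nrow(ch)) stop("no choice map for edge ", e)
      if (!.isLeafKey(s)) {
        for (slot in c("leftChildEdge", "rightChildEdge")) {
          side <- if (slot == "leftChildEdge") "left" else "right"
          pref <- paste(s, side, "")
          if (!any(startsWith(G, pref))) {
            sel <- ch[[slot]]
            if (is.na(sel)) stop("undefined ", slot, " choice at edge ", e)
            addEdge(sel); grew <- TRUE
          }
        }
      }
      if (!.isRhoKey(t)) {
        hasParent <- any(vapply(G, function(k)
          strsplit(k, " ", fixed = TRUE)[[1]][3L] == t, TRUE))
        if (!hasParent) {
          sel <- ch$parentEdge
          if (is.na(sel)) stop("undefined parent choice at edge ", e)
          addEdge(sel); grew <- TRUE
        }
        sibPref <- paste(t, .otherSide(w), "")
        if (!any(startsWith(G, sibPref))) {
          sel <- ch$siblingEdge
          if (is.na(sel)) stop("undefined sibling choice at edge ", e)
          addEdge(sel); grew <- TRUE
        }
      }
    }
    if (!grew) break
  }
  sort(G, method = "radix")
}

#' Best known tree for an sDAG edge
#'
#' Starting from the given edge, recursively applies the leafward choice map
#' to fill in missing children and the rootward choice map to fill in a
#' missing parent and sibling, until the grown edge set is a tree on the full
#' taxon set. Branch lengths are the sDAG's stored lengths.
#'
#' @param state a [TPState-class] (or pass `d`/`choice` internally).
#' @param edge an edge key of the sDAG.
#' @return a rooted bifurcating phylo object contained in the sDAG.
#' @export
bestKnownTree <- function(state, edge) {
  keys <- .bestKnownTreeKeys(state@sdag, state@choice, edge)
  rows <- match(keys, state@sdag@edges$key)
  if (anyNA(rows)) stop("choice map selected an edge absent from the sDAG")
  ed <- state@sdag@edges[rows, , drop = FALSE]
  .edgeSetToPhylo(ed, state@sdag@taxa, withLengths = TRUE)
}

## BKT log likelihood (errors on sentinel lengths via treeLogLikelihood)
.bktLogLik <- function(d, choice, edge, caln) {
  keys <- .bestKnownTreeKeys(d, choice, edge)
  ed <- d@edges[match(keys, d@edges$key), , drop = FALSE]
  if (anyNA(ed$length[!vapply(ed$parent, .isRhoKey, TRUE)]))
    stop("best known tree for ", edge, " touches unset (sentinel) lengths")
  treeLogLikelihood(.edgeSetToPhylo(ed, d@taxa, withLengths = TRUE), caln)
}

## ---- argmax extension of choice maps -------------------------------------

## candidate edges per slot for edge e in sDAG d
.slotCandidates <- function(d, idx, e, slot) {
  parts <- strsplit(e, " ", fixed = TRUE)[[1]]
  t <- parts[1L]; w <- parts[2L]; s <- parts[3L]
  ed <- d@edges
  if (slot == "parentEdge") {
    if (.isRhoKey(t)) return(character())
    return(ed$key[idx$parentRows[[t]]])
  }
  if (slot == "siblingEdge") {
    if (.isRhoKey(t)) return(character())
    return(ed$key[idx$childRows[[paste(t, .otherSide(w))]]])
  }
  if (.isLeafKey(s)) return(character())
  side <- if (slot == "leftChildEdge") "left" else "right"
  if (grepl("^0*$", .sideKey(s, side))) return(character())
  ed$key[idx$childRows[[paste(s, side)]]]
}

## Extend choice maps over newEdges by slot-wise greedy argmax: every unset
## slot is first seeded with its first candidate (canonical edge order), then
## each slot of each new edge, in order (parent+sibling jointly, then left
## child, then right child), is set to the candidate maximizing the best-
## known-tree log likelihood of that edge. Ties keep the earlier candidate.
## Lengths: sentinel lengths among newEdges are initialized to
## config$newEdgeInit first; when optimizeLengths is TRUE each new edge's
## length is then optimized (Brent) against its own best-known-tree
## likelihood, sweeping in canonical order.
.extendChoicesArgmax <- function(d, choice, newEdges, caln, config,
                                 optimizeLengths = TRUE,
                                 optimizeOnly = NULL) {
  if (!length(newEdges)) return(list(sdag = d, choice = choice))
  idx <- .sdagIndex(d)
  newEdges <- newEdges[order(vapply(newEdges, function(k) {
    p <- strsplit(k, " ", fixed = TRUE)[[1]]
    .edgeSortKey(p[1L], p[2L], p[3L])
  }, ""), method = "radix")]
  ## ensure rows exist; seed every unset slot with the first candidate
  for (e in newEdges) {
    if (!(e %in% rownames(choice))) {
      row <- .choiceRow(); rownames(row) <- e
      choice <- rbind(choice, row)
    }
    for (slot in c("parentEdge", "siblingEdge", "leftChildEdge", "rightChildEdge")) {
      if (!is.na(choice[e, slot])) next
      cand <- .slotCandidates(d, idx, e, slot)
      if (length(cand)) choice[e, slot] <- cand[1L]
    }
  }
  ## initialize sentinel lengths on the new edges
  rows <- match(newEdges, d@edges$key)
  isRho <- vapply(d@edges$parent[rows], .isRhoKey, TRUE)
  d@edges$length[rows[isRho]] <- 0
  fill <- rows[!isRho & is.na(d@edges$length[rows])]
  d@edges$length[fill] <- config$newEdgeInit
  ## slot-wise greedy argmax
  for (e in newEdges) {
    groups <- list(c("parentEdge", "siblingEdge"),
                   "leftChildEdge", "rightChildEdge")
    for (slots in groups) {
      cands <- lapply(slots, function(sl) .slotCandidates(d, idx, e, sl))
      if (!all(lengths(cands) > 0L)) next
      combos <- expand.grid(cands, stringsAsFactors = FALSE)
      if (nrow(combos) <= 1L) next
      best <- -Inf; bestIdx <- 1L
      for (i in seq_len(nrow(combos))) {
        for (j in seq_along(slots)) choice[e, slots[j]] <- combos[i, j]
        ll <- .bktLogLik(d, choice, e, caln)
        if (ll > best + 1e-12) { best <- ll; bestIdx <- i }
      }
      for (j in seq_along(slots)) choice[e, slots[j]] <- combos[bestIdx, j]
    }
  }
  if (optimizeLengths) {
    targets <- if (is.null(optimizeOnly)) newEdges
               else intersect(newEdges, optimizeOnly)
    for (e in targets) {
      r <- match(e, d@edges$key)
      if (.isRhoKey(d@edges$parent[r])) next
      fi <- function(v) {
        d@edges$length[r] <- v
        .bktLogLik(d, choice, e, caln)
      }
      opt <- stats::optimize(fi, lower = config$brlenLower,
                             upper = config$brlenUpper, maximum = TRUE,
                             tol = config$brlenTol)
      cand <- c(opt$maximum, d@edges$length[r], config$brlenLower)
      vals <- c(opt$objective, fi(d@edges$length[r]), fi(config$brlenLower))
      d@edges$length[r] <- cand[which.max(vals)]
    }
  }
  list(sdag = d, choice = choice)
}

#' Extend choice maps over new edges with the argmax strategy
#'
#' Each unresolved choice slot of each new edge (the parent+sibling pair
#' jointly, then the left child, then the right child) is filled by the
#' candidate maximizing the log likelihood of the resulting best known tree,
#' candidates drawn from the existing incident edges; ties are broken by edge
#' order. New-edge branch lengths are then optimized against their own
#' best-known-tree likelihood. Idempotent when `newEdges` is empty.
#'
#' @param state a [TPState-class].
#' @param newEdges character vector of edge keys already present in the sDAG.
#' @return the updated [TPState-class].
#' @export
extendArgmax <- function(state, newEdges) {
  res <- .extendChoicesArgmax(state@sdag, state@choice, newEdges,
                              state@caln, state@config)
  state@sdag <- res$sdag
  state@choice <- res$choice
  state
}

## ---- initialization ------------------------------------------------------

#' Initialize a top-pruning state from a likelihood-ordered tree list
#'
#' Builds the sDAG spanned by the topologies; each edge's branch length and
#' choice-map neighbors come from the first (highest-likelihood) listed tree
#' containing that edge. Then all compatible edges are added, their choices
#' assigned by the argmax strategy and their lengths optimized against their
#' best known trees.
#'
#' @param trees list of phylo objects with branch lengths, ordered by
#'   decreasing [treeLogLikelihood()].
#' @param aln an alignment covering the trees' taxa.
#' @param verify check the likelihood ordering and error if violated.
#' @param config see [sdagConfig()].
#' @param taxa optional taxon universe.
#' @return a [TPState-class] with an empty queue.
#' @export
initTopPruning <- function(trees, aln, verify = FALSE, config = sdagConfig(),
                           taxa = NULL) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (!length(trees)) stop("need at least one starting tree")
  d <- sdagFromTopologies(trees, taxa)
  caln <- .compressAlignment(aln, d@taxa)
  if (verify) {
    lls <- vapply(trees, treeLogLikelihood, 0, aln = caln)
    if (any(diff(lls) > 1e-9))
      stop("trees are not ordered by decreasing likelihood")
  }
  ## choice maps from the first tree containing each edge
  choice <- .choiceRow()[0, , drop = FALSE]
  for (tr in trees) {
    tc <- .treeChoices(.phyloToTtree(tr, d@taxa))
    tc <- tc[!(rownames(tc) %in% rownames(choice)), , drop = FALSE]
    choice <- rbind(choice, tc)
  }
  comp <- completeEdges(d)
  d <- comp$sdag
  newKeys <- setdiff(d@edges$key, rownames(choice))
  res <- .extendChoicesArgmax(d, choice, newKeys, caln, config)
  new("TPState", sdag = res$sdag, choice = res$choice,
      queue = .emptyTpQueue(), caln = caln, config = config)
}

.emptyTpQueue <- function() {
  data.frame(source = character(), swap = character(), tPrime = character(),
             sPrime = character(), centralWhich = character(),
             central = character(), enlarging = logical(),
             tpLogLik = numeric(), stringsAsFactors = FALSE)
}

## ---- NNI evaluation ------------------------------------------------------

## Evaluate proposal p against state: hypothetical overlay with
## around-new-nodes completion, argmax choice extension over the new edges,
## then the central edge's length optimized against its best known tree.
## Returns list(ll, sdag, choice, newEdges).
.tpEvalProposal <- function(state, p, optimizeLengths = TRUE) {
  d <- state@sdag
  ap <- applyNNI(d, p, "around_new_nodes")
  d2 <- ap$sdag
  rows <- match(ap$newEdges$key, d2@edges$key)
  for (i in seq_along(rows)) {
    from <- ap$newEdges$from[i]
    if (!is.na(from)) {
      fr <- match(from, d@edges$key)
      if (!is.na(fr)) d2@edges$length[rows[i]] <- d@edges$length[fr]
    }
  }
  optimizeOnly <- if (isTRUE(state@config$optimizeAllNewEdges)) NULL
                  else p$central
  res <- .extendChoicesArgmax(d2, state@choice, ap$newEdges$key, state@caln,
                              state@config, optimizeLengths = optimizeLengths,
                              optimizeOnly = optimizeOnly)
  ll <- .bktLogLik(res$sdag, res$choice, p$central, state@caln)
  list(ll = ll, sdag = res$sdag, choice = res$choice,
       newEdges = ap$newEdges$key)
}

#' Top-pruning likelihood of an NNI proposal
#'
#' The log likelihood of the best known tree for the central edge of the NNI,
#' evaluated in the hypothetical post-NNI sDAG with the central edge's branch
#' length optimized (other lengths fixed). The state is not modified.
#'
#' @param state a [TPState-class].
#' @param p a proposal row from [candidateNNIs()].
#' @param aln ignored (the state's alignment is used); retained for symmetry.
#' @return log likelihood (scalar).
#' @export
tpLikelihood <- function(state, p, aln = NULL) {
  if (is.data.frame(p)) p <- as.list(p[1L, ])
  .tpEvalProposal(state, p)$ll
}

## ---- the search ----------------------------------------------------------

#' Top-pruning NNI search
#'
#' The iterative search: initialize via [initTopPruning()], rank all
#' enlarging NNI proposals by top-pruning likelihood, then repeatedly apply
#' the best proposal (with full edge completion), assign choices and lengths
#' to the new edges by the argmax strategy, and insert newly enabled
#' proposals with freshly computed likelihoods (cached entries are never
#' updated). Stops after `maxIterations` or when every queued likelihood is
#' below `likelihoodThreshold`.
#'
#' @inheritParams initTopPruning
#' @param maxIterations iteration cap.
#' @param likelihoodThreshold stop once the best queued top-pruning
#'   likelihood falls below this (`Inf` performs no iterations).
#' @return list with `state` (final [TPState-class]), `sdag`, and `trace`
#'   (data.frame: `iteration`, `central`, `tpLogLik`, `nNodes`, `nEdges`,
#'   `nTopologies`).
#' @export
tpSearch <- function(trees, aln, maxIterations = 10L,
                     likelihoodThreshold = -Inf, verify = FALSE,
                     config = sdagConfig(), taxa = NULL) {
  state <- initTopPruning(trees, aln, verify = verify, config = config,
                          taxa = taxa)
  state@queue <- .tpAddProposals(state, state@queue)
  trace <- data.frame()
  iter <- 0L
  while (iter < maxIterations && nrow(state@queue)) {
    q <- state@queue
    q <- q[order(-q$tpLogLik, .edgeSortKey(q$tPrime, q$centralWhich, q$sPrime),
                 method = "radix"), , drop = FALSE]
    if (q$tpLogLik[1L] < likelihoodThreshold) { state@queue <- q; break }
    p <- as.list(q[1L, ])
    state@queue <- q[-1L, , drop = FALSE]
    if (!.nniEnlarges(state@sdag, p)) next
    ## enlarge with full completion; assign choices and lengths to all new
    ## edges (argmax + best-known-tree optimized lengths)
    ap <- applyNNI(state@sdag, p, "full")
    d2 <- ap$sdag
    rows <- match(ap$newEdges$key, d2@edges$key)
    for (i in seq_along(rows)) {
      from <- ap$newEdges$from[i]
      if (!is.na(from)) {
        fr <- match(from, state@sdag@edges$key)
        if (!is.na(fr)) d2@edges$length[rows[i]] <- state@sdag@edges$length[fr]
      }
    }
    res <- .extendChoicesArgmax(d2, state@choice, ap$newEdges$key,
                                state@caln, state@config)
    state@sdag <- res$sdag
    state@choice <- res$choice
    iter <- iter + 1L
    trace <- rbind(trace, data.frame(
      iteration = iter, central = p$central, tpLogLik = p$tpLogLik,
      nNodes = length(state@sdag@nodes), nEdges = nrow(state@sdag@edges),
      nTopologies = countTopologies(state@sdag), stringsAsFactors = FALSE))
    state@queue <- .tpAddProposals(state, state@queue)
  }
  list(state = state, sdag = state@sdag, trace = trace)
}

## insert newly enabled enlarging proposals, leaving cached entries untouched
.tpAddProposals <- function(state, queue) {
  cand <- candidateNNIs(state@sdag)
  if (!nrow(cand)) return(queue)
  seen <- if (nrow(queue)) paste(queue$tPrime, queue$sPrime) else character()
  cand <- cand[!(paste(cand$tPrime, cand$sPrime) %in% seen), , drop = FALSE]
  if (!nrow(cand)) return(queue)
  cand$tpLogLik <- vapply(seq_len(nrow(cand)), function(i)
    .tpEvalProposal(state, as.list(cand[i, ]))$ll, 0)
  rbind(queue, cand)
}
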