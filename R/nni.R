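## NNI operations that enlarge an sDAG: candidate generation (two proposals
## per eligible edge), application with the three new-edge classes, and
## post-NNI completion policies.

## An NNI proposal is a one-row data.frame (or a list) with fields:
##   source  - edge key (t, w) -> s the proposal was generated from
##   swap    - "left"/"right": which clade of s is swapped with t's sibling clade
##   tPrime, sPrime - new subsplit keys
##   centralWhich   - clade of tPrime partitioned by sPrime
##   central        - edge key tPrime -> sPrime

## derive (tPrime, sPrime) for one swap variant of edge (t, w) -> s.
## With t = {X u Y, Z} (Z the clade of t other than w) and s = {X, Y}:
## swapping clade B of s with Z keeps A = other clade of s, giving
## tPrime = {A u Z, B}, sPrime = {A, Z}.
.nniDerive <- function(parent, which, child, swap) {
  zKey <- .sideKey(parent, .otherSide(which))
  bKey <- .sideKey(child, swap)
  aKey <- .sideKey(child, .otherSide(swap))
  z <- .keyBits(zKey); b <- .keyBits(bKey); a <- .keyBits(aKey)
  mk <- function(k1, k2) {
    if (.cladeSortKey(k1) <= .cladeSortKey(k2)) .subsplitKey(k1, k2)
    else .subsplitKey(k2, k1)
  }
  az <- .cladeKey(a | z)
  tPrime <- mk(az, bKey)
  sPrime <- mk(aKey, zKey)
  centralWhich <- if (.sideKey(tPrime, "left") == az) "left" else "right"
  list(tPrime = tPrime, sPrime = sPrime, centralWhich = centralWhich,
       central = .edgeKey(tPrime, centralWhich, sPrime))
}

#' NNI proposals of an sDAG
#'
#' Generates the two swap variants for every eligible edge (parent not rho and
#' child subsplit internal), deduplicates by the derived `(tPrime, sPrime)`
#' pair (first generated wins, edges in canonical order), and by default drops
#' proposals that would not enlarge the sDAG.
#'
#' @param d a [SubsplitDAG-class].
#' @param onlyEnlarging drop proposals adding no new node and no new edge key
#'   (the default, matching the search algorithms).
#' @param dedupe collapse distinct source edges proposing the same enlargement.
#' @return a data.frame with columns `source`, `swap`, `tPrime`, `sPrime`,
#'   `centralWhich`, `central`, `enlarging`.
#' @export
candidateNNIs <- function(d, onlyEnlarging = TRUE, dedupe = TRUE) {
  ed <- d@edges
  rows <- list()
  for (r in seq_len(nrow(ed))) {
    if (.isRhoKey(ed$parent[r])) next
    parts <- .subsplitParts(ed$child[r])
    if (grepl("^0*$", parts[1L]) || grepl("^0*$", parts[2L])) next
    for (swap in c("left", "right")) {
      der <- .nniDerive(ed$parent[r], ed$which[r], ed$child[r], swap)
      rows[[length(rows) + 1L]] <- data.frame(
        source = ed$key[r], swap = swap, tPrime = der$tPrime,
        sPrime = der$sPrime, centralWhich = der$centralWhich,
        central = der$central, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(source = character(), swap = character(),
                      tPrime = character(), sPrime = character(),
                      centralWhich = character(), central = character(),
                      enlarging = logical(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  if (dedupe) out <- out[!duplicated(paste(out$tPrime, out$sPrime)), , drop = FALSE]
  out$enlarging <- vapply(seq_len(nrow(out)), function(i)
    .nniEnlarges(d, out[i, , drop = FALSE]), TRUE)
  if (onlyEnlarging) out <- out[out$enlarging, , drop = FALSE]
  rownames(out) <- NULL
  out
}

## would applying p add at least one node or edge key?
.nniEnlarges <- function(d, p) {
  if (!(p$tPrime %in% d@nodes) || !(p$sPrime %in% d@nodes)) return(TRUE)
  nrow(.nniNewEdges(d, p)) > 0L
}

## the class (a)/(b)/(c) edges of proposal p not already in d, with the
## pre-NNI counterpart edge key each was derived from (NA for the central
## edge). Does not include completion edges.
.nniNewEdges <- function(d, p) {
  src <- strsplit(p$source, " ", fixed = TRUE)[[1]]
  t <- src[1L]; w <- src[2L]; s <- src[3L]
  zWhich <- .otherSide(w)
  aKey <- .sideKey(p$sPrime, if (.sideKey(p$sPrime, "left") == .sideKey(t, zWhich)) "right" else "left")
  ## clade roles: A = clade shared by s and sPrime; B = clade shared by s and
  ## tPrime; Z = clade shared by t and sPrime
  zKey <- .sideKey(t, zWhich)
  bKey <- .sideKey(p$tPrime, if (.sideKey(p$tPrime, "left") == .subsplitUnion(p$sPrime)) "right" else "left")
  ed <- d@edges
  out <- data.frame(parent = p$tPrime, which = p$centralWhich, child = p$sPrime,
                    from = NA_character_, stringsAsFactors = FALSE)
  addFrom <- function(out, parent, which, child, from) {
    rbind(out, data.frame(parent = parent, which = which, child = child,
                          from = from, stringsAsFactors = FALSE))
  }
  ## (b) parents of tPrime: u -> tPrime for all u -> t (same clade of u)
  pr <- which(ed$child == t)
  for (r in pr) out <- addFrom(out, ed$parent[r], ed$which[r], p$tPrime, ed$key[r])
  sideOf <- function(node, cladeKey) {
    if (.sideKey(node, "left") == cladeKey) "left" else "right"
  }
  ## (c) descendants of the new subsplit-clades
  for (r in which(ed$parent == s & ed$which == sideOf(s, aKey)))
    out <- addFrom(out, p$sPrime, sideOf(p$sPrime, aKey), ed$child[r], ed$key[r])
  for (r in which(ed$parent == s & ed$which == sideOf(s, bKey)))
    out <- addFrom(out, p$tPrime, sideOf(p$tPrime, bKey), ed$child[r], ed$key[r])
  for (r in which(ed$parent == t & ed$which == zWhich))
    out <- addFrom(out, p$sPrime, sideOf(p$sPrime, zKey), ed$child[r], ed$key[r])
  out$key <- .edgeKey(out$parent, out$which, out$child)
  out <- out[!duplicated(out$key), , drop = FALSE]
  out[!(out$key %in% ed$key), , drop = FALSE]
}

## completion edges touching the given nodes (parent or child in `around`)
## that are compatible but absent; returns data.frame parent/which/child
.completionEdgesAround <- function(d, around) {
  idx <- .sdagIndex(d)
  have <- new.env(parent = emptyenv(), hash = TRUE)
  for (k in d@edges$key) have[[k]] <- TRUE
  res <- list()
  push <- function(p, w, c) {
    k <- .edgeKey(p, w, c)
    if (is.null(have[[k]]) && .keyValidChild(p, w, c)) {
      have[[k]] <- TRUE
      res[[length(res) + 1L]] <<- data.frame(parent = p, which = w, child = c,
                                             stringsAsFactors = FALSE)
    }
  }
  for (nd in around) {
    ## nd as parent
    if (!.isLeafKey(nd)) for (w in c("left", "right")) {
      clade <- .sideKey(nd, w)
      if (grepl("^0*$", clade)) next
      for (c in idx$nodesByUnion[[clade]]) push(nd, w, c)
    }
    ## nd as child
    u <- .subsplitUnion(nd)
    for (p in d@nodes) {
      if (.isLeafKey(p)) next
      for (w in c("left", "right")) if (.sideKey(p, w) == u) push(p, w, nd)
    }
  }
  if (!length(res)) data.frame(parent = character(), which = character(),
                               child = character(), stringsAsFactors = FALSE)
  else do.call(rbind, res)
}

#' Apply an NNI proposal to an sDAG
#'
#' Adds the new subsplits `tPrime` and `sPrime` (if absent) and the three
#' classes of edges: (a) the central edge `tPrime -> sPrime`; (b) a parent
#' edge `u -> tPrime` for every existing `u -> t`; (c) descendant edges
#' mirroring, clade by clade, the existing children of `s` and of `t`'s
#' swapped clade. Then completes edges according to `completion`:
#' `"around_new_nodes"` adds every compatible missing edge incident to
#' `tPrime` or `sPrime`; `"full"` runs [completeEdges()] on the result. All
#' added edges carry the NA branch-length sentinel; pre-NNI content is
#' untouched.
#'
#' @param d a [SubsplitDAG-class].
#' @param p one proposal row from [candidateNNIs()].
#' @param completion `"around_new_nodes"` or `"full"`.
#' @return a list with `sdag` (the enlarged sDAG) and `newEdges` (data.frame
#'   of added edges with columns `parent`, `which`, `child`, `key`, `from`;
#'   `from` is the pre-NNI counterpart edge key or NA).
#' @export
applyNNI <- function(d, p, completion = c("around_new_nodes", "full")) {
  completion <- match.arg(completion)
  if (is.data.frame(p)) p <- as.list(p[1L, ])
  src <- strsplit(p$source, " ", fixed = TRUE)[[1]]
  if (!(src[1L] %in% d@nodes) || !(src[3L] %in% d@nodes))
    stop("proposal references subsplits absent from the sDAG")
  abc <- .nniNewEdges(d, p)
  ed <- d@edges[, c("parent", "which", "child", "length")]
  if (nrow(abc))
    ed <- rbind(ed, data.frame(parent = abc$parent, which = abc$which,
                               child = abc$child, length = NA_real_,
                               stringsAsFactors = FALSE))
  d2 <- .newSdag(d@taxa, ed)
  added <- abc[, c("parent", "which", "child", "from")]
  if (completion == "full") {
    comp <- completeEdges(d2)
    compKeys <- setdiff(comp$sdag@edges$key, d2@edges$key)
    d2 <- comp$sdag
    if (length(compKeys)) {
      ck <- do.call(rbind, strsplit(compKeys, " ", fixed = TRUE))
      added <- rbind(added, data.frame(parent = ck[, 1L], which = ck[, 2L],
                                       child = ck[, 3L], from = NA_character_,
                                       stringsAsFactors = FALSE))
    }
  } else {
    comp <- .completionEdgesAround(d2, unique(c(p$tPrime, p$sPrime)))
    if (nrow(comp)) {
      ed2 <- rbind(d2@edges[, c("parent", "which", "child", "length")],
                   data.frame(parent = comp$parent, which = comp$which,
                              child = comp$child, length = NA_real_,
                              stringsAsFactors = FALSE))
      d2 <- .newSdag(d@taxa, ed2)
      added <- rbind(added, data.frame(parent = comp$parent, which = comp$which,
                                       child = comp$child, from = NA_character_,
                                       stringsAsFactors = FALSE))
    }
  }
  added$key <- .edgeKey(added$parent, added$which, added$child)
  added <- added[!duplicated(added$key), , drop = FALSE]
  rownames(added) <- NULL
  list(sdag = d2, newEdges = added)
}
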