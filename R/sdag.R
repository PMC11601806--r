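## The subsplit DAG: construction from rooted topologies, compatible-edge
## completion, topology membership, counting and enumeration, serialization.

#' Subsplit directed acyclic graph
#'
#' An sDAG has subsplits as nodes and directed edges connecting a parent
#' subsplit to child subsplits partitioning one of its clades. It compactly
#' represents a set of rooted bifurcating topologies: every tree-structured
#' subgraph containing all leaves is one topology. Each edge carries a single
#' branch length (NA is the "unset" sentinel for edges added by completion),
#' so topologies in the sDAG correspond one-to-one to trees.
#'
#' @slot taxa character, the ordered taxon universe.
#' @slot nodes character vector of subsplit keys (including rho and all leaf
#'   subsplits), in subsplit order.
#' @slot edges data.frame with columns `parent`, `which`, `child`, `length`,
#'   `key`, one row per edge, sorted by edge order. Edges from rho carry
#'   length 0 and are excluded from likelihood products.
#' @export
setClass("SubsplitDAG",
         representation(taxa = "character", nodes = "character", edges = "data.frame"))

setValidity("SubsplitDAG", function(object) {
  ed <- object@edges
  n <- length(object@taxa)
  if (anyDuplicated(ed$key)) return("duplicate edge keys")
  for (r in seq_len(nrow(ed)))
    if (!.keyValidChild(ed$parent[r], ed$which[r], ed$child[r]))
      return(paste0("invalid edge: ", ed$key[r]))
  leaves <- vapply(seq_len(n), .leafKey, "", n = n)
  if (!all(leaves %in% object@nodes)) return("missing leaf subsplit(s)")
  if (!.rhoKey(n) %in% object@nodes) return("missing universal ancestor")
  ## every non-leaf node's nonempty clades have outdegree >= 1; reachability
  hasChild <- unique(paste(ed$parent, ed$which))
  for (nd in object@nodes) {
    if (.isLeafKey(nd)) next
    for (w in c("left", "right")) {
      if (grepl("^0*$", .sideKey(nd, w))) next
      if (!(paste(nd, w) %in% hasChild))
        return(paste0("node ", nd, " has no outgoing edge at clade ", w))
    }
  }
  reached <- .rhoKey(n)
  frontier <- reached
  while (length(frontier)) {
    nxt <- setdiff(unique(ed$child[ed$parent %in% frontier]), reached)
    reached <- c(reached, nxt)
    frontier <- nxt
  }
  if (!all(object@nodes %in% reached)) return("node(s) unreachable from rho")
  TRUE
})

## internal constructor: sorts, dedups (first occurrence wins), derives nodes
.newSdag <- function(taxa, edges, validate = FALSE) {
  edges$key <- .edgeKey(edges$parent, edges$which, edges$child)
  edges <- edges[!duplicated(edges$key), , drop = FALSE]
  edges <- edges[order(.edgeSortKey(edges$parent, edges$which, edges$child),
                       method = "radix"), , drop = FALSE]
  rownames(edges) <- NULL
  n <- length(taxa)
  nodes <- unique(c(.rhoKey(n), edges$parent, edges$child,
                    vapply(seq_len(n), .leafKey, "", n = n)))
  nodes <- nodes[order(.subsplitSortKey(nodes), method = "radix")]
  d <- new("SubsplitDAG", taxa = taxa, nodes = nodes, edges = edges)
  if (validate) methods::validObject(d)
  d
}

## fast lookup index: children rows per (node, which), parent rows per node,
## node keys per clade-union, plus hoisted per-node string predicates
.sdagIndex <- function(d) {
  ed <- d@edges
  nodes <- d@nodes
  unions <- vapply(nodes, .subsplitUnion, "")
  left <- vapply(nodes, .sideKey, "", which = "left")
  right <- vapply(nodes, .sideKey, "", which = "right")
  isLeaf <- vapply(nodes, .isLeafKey, TRUE)
  isRho <- vapply(nodes, .isRhoKey, TRUE)
  usize <- vapply(unions, function(u) sum(.keyBits(u)), 0)
  names(unions) <- names(left) <- names(right) <- nodes
  names(isLeaf) <- names(isRho) <- names(usize) <- nodes
  list(
    childRows = split(seq_len(nrow(ed)), paste(ed$parent, ed$which)),
    parentRows = split(seq_len(nrow(ed)), ed$child),
    nodesByUnion = split(nodes, unions),
    rowByKey = stats::setNames(seq_len(nrow(ed)), ed$key),
    unions = unions, left = left, right = right,
    isLeaf = isLeaf, isRho = isRho, usize = usize,
    nodesAsc = nodes[order(usize)]
  )
}

## ---- accessors -----------------------------------------------------------

#' @describeIn SubsplitDAG-class taxon universe of the sDAG.
#' @param d a SubsplitDAG.
#' @export
sdagTaxa <- function(d) d@taxa

#' @describeIn SubsplitDAG-class subsplit node keys (bitstring form).
#' @export
sdagNodes <- function(d) d@nodes

#' @describeIn SubsplitDAG-class edge table (parent/which/child keys, length, key).
#' @export
sdagEdges <- function(d) d@edges

#' @describeIn SubsplitDAG-class human-readable node labels such as `"2|3,4,5"`.
#' @export
sdagNodeLabels <- function(d) vapply(d@nodes, .subsplitLabel, "", taxa = d@taxa)

#' @describeIn SubsplitDAG-class internal (non-leaf, non-rho) subsplit keys.
#' @export
internalSubsplits <- function(d) {
  keep <- !vapply(d@nodes, .isLeafKey, TRUE) & !vapply(d@nodes, .isRhoKey, TRUE)
  d@nodes[keep]
}

setMethod("show", "SubsplitDAG", function(object) {
  cat("SubsplitDAG on ", length(object@taxa), " taxa: ",
      length(object@nodes), " nodes, ", nrow(object@edges), " edges, ",
      format(countTopologies(object), big.mark = ","), " topologies\n", sep = "")
})

## ---- construction --------------------------------------------------------

#' Build an sDAG from rooted topologies
#'
#' The sDAG of a list of topologies is the union of the nodes and edges of the
#' single-topology sDAGs. Each edge's branch length is taken from the first
#' listed tree containing that edge.
#'
#' @param topologies a list of rooted bifurcating phylo objects (or a single
#'   phylo) on the same taxon set.
#' @param taxa optional taxon universe; default is inferred from the first tree.
#' @return a [SubsplitDAG-class].
#' @export
sdagFromTopologies <- function(topologies, taxa = NULL) {
  if (inherits(topologies, "phylo")) topologies <- list(topologies)
  if (!length(topologies)) stop("need at least one topology")
  if (is.null(taxa)) taxa <- treeTaxa(topologies[[1L]])
  labelSets <- lapply(topologies, function(p) sort(p$tip.label, method = "radix"))
  for (ls in labelSets)
    if (!identical(ls, sort(taxa, method = "radix")))
      stop("topologies are on mixed taxon sets")
  parts <- lapply(topologies, .phyloToTtree, taxa = taxa)
  .newSdag(taxa, do.call(rbind, parts))
}

#' Add all edges between compatible subsplits
#'
#' For every ordered node pair `(p, c)` and clade `w` with a valid parent-child
#' relation, ensures the edge exists. Added edges carry the NA branch-length
#' sentinel; callers must assign lengths before any likelihood touches them.
#' Idempotent.
#'
#' @param d a [SubsplitDAG-class].
#' @return a list with elements `sdag` (the completed sDAG) and `added`
#'   (integer count of edges added).
#' @export
completeEdges <- function(d) {
  idx <- .sdagIndex(d)
  have <- new.env(parent = emptyenv(), hash = TRUE)
  for (k in d@edges$key) have[[k]] <- TRUE
  addP <- character(); addW <- character(); addC <- character()
  for (p in d@nodes) {
    if (.isLeafKey(p)) next
    for (w in c("left", "right")) {
      clade <- .sideKey(p, w)
      if (grepl("^0*$", clade)) next
      for (c in idx$nodesByUnion[[clade]]) {
        if (!.keyValidChild(p, w, c)) next
        k <- .edgeKey(p, w, c)
        if (is.null(have[[k]])) {
          addP <- c(addP, p); addW <- c(addW, w); addC <- c(addC, c)
          have[[k]] <- TRUE
        }
      }
    }
  }
  if (!length(addP)) return(list(sdag = d, added = 0L))
  newEdges <- rbind(d@edges[, c("parent", "which", "child", "length")],
                    data.frame(parent = addP, which = addW, child = addC,
                               length = NA_real_, stringsAsFactors = FALSE))
  list(sdag = .newSdag(d@taxa, newEdges), added = length(addP))
}

## ---- counting and enumeration -------------------------------------------

#' Count the topologies contained in an sDAG
#'
#' Dynamic program over nodes: `n(s)` is the product over s's nonempty clades
#' of the sum of `n(child)` over outgoing edges at that clade; leaves count 1
#' and empty clades contribute factor 1. The total is the clade-sum at rho.
#'
#' @param d a [SubsplitDAG-class].
#' @return numeric count (exact for all desk-scale sDAGs).
#' @export
countTopologies <- function(d) {
  idx <- .sdagIndex(d)
  below <- .sdagBelowCounts(d, idx)
  cladeSum <- function(node, w) {
    rows <- idx$childRows[[paste(node, w)]]
    if (is.null(rows)) return(1)
    sum(below[d@edges$child[rows]])
  }
  cladeSum(.rhoKey(length(d@taxa)), "right")
}

## per-node subtree counts n(s); nodes processed by ascending union size
.sdagBelowCounts <- function(d, idx = .sdagIndex(d)) {
  below <- stats::setNames(numeric(length(d@nodes)), d@nodes)
  empty <- .emptyKey(length(d@taxa))
  for (nd in idx$nodesAsc) {
    if (idx$isLeaf[[nd]]) { below[nd] <- 1; next }
    if (idx$isRho[[nd]]) next
    val <- 1
    for (w in c("left", "right")) {
      if (idx[[w]][[nd]] == empty) next
      rows <- idx$childRows[[paste(nd, w)]]
      val <- val * (if (is.null(rows)) 0 else sum(below[d@edges$child[rows]]))
    }
    below[nd] <- val
  }
  below
}

#' Enumerate topologies of an sDAG
#'
#' Topologies are produced in a deterministic order (lexicographic by chosen
#' edges, edges in canonical order). Trees carry the sDAG's stored branch
#' lengths (unset sentinel edges become 0).
#'
#' @param d a [SubsplitDAG-class].
#' @param limit maximum number of topologies to return (default all).
#' @param cap safety cap on the total enumeration size.
#' @return a list of phylo objects.
#' @export
enumerateTopologies <- function(d, limit = Inf, cap = 1e5) {
  if (limit < 1) stop("limit must be >= 1")
  total <- countTopologies(d)
  if (total > cap) stop("sDAG contains ", total, " topologies; enumeration cap is ", cap)
  idx <- .sdagIndex(d)
  memo <- new.env(parent = emptyenv(), hash = TRUE)
  enumNode <- function(nd) {
    got <- memo[[nd]]
    if (!is.null(got)) return(got)
    if (.isLeafKey(nd)) { memo[[nd]] <- list(integer()); return(list(integer())) }
    sides <- list()
    for (w in c("left", "right")) {
      if (grepl("^0*$", .sideKey(nd, w))) next
      rows <- idx$childRows[[paste(nd, w)]]
      opts <- list()
      for (r in rows)
        for (sub in enumNode(d@edges$child[r]))
          opts[[length(opts) + 1L]] <- c(r, sub)
      sides[[length(sides) + 1L]] <- opts
    }
    out <- sides[[1L]]
    if (length(sides) == 2L) {
      comb <- list()
      for (a in sides[[1L]]) for (b in sides[[2L]])
        comb[[length(comb) + 1L]] <- c(a, b)
      out <- comb
    }
    memo[[nd]] <- out
    out
  }
  rhoRows <- idx$childRows[[paste(.rhoKey(length(d@taxa)), "right")]]
  res <- list()
  for (r in rhoRows) {
    for (sub in enumNode(d@edges$child[r])) {
      res[[length(res) + 1L]] <- c(r, sub)
      if (length(res) >= limit) break
    }
    if (length(res) >= limit) break
  }
  lapply(res, function(rows) {
    ed <- d@edges[rows, , drop = FALSE]
    ed$length[is.na(ed$length)] <- 0
    .edgeSetToPhylo(ed, d@taxa, withLengths = TRUE)
  })
}

#' Test whether an sDAG contains a topology
#'
#' True iff every edge of the topology's single-tree sDAG representation is
#' present in `d` (by edge key; branch lengths are ignored).
#'
#' @param d a [SubsplitDAG-class].
#' @param phy a rooted bifurcating phylo object on the same taxa.
#' @return logical.
#' @export
containsTopology <- function(d, phy) {
  if (!setequal(phy$tip.label, d@taxa))
    stop("topology and sDAG are on different taxon sets")
  keys <- .phyloToTtree(phy, d@taxa)$key
  all(keys %in% d@edges$key)
}

## ---- serialization -------------------------------------------------------

#' Write an sDAG to a line-oriented text file
#'
#' First line: `#taxa<TAB>label,label,...` (universe order). Then one edge per
#' line: `parent<TAB>which<TAB>child<TAB>branch_length`, with subsplits printed
#' as `leftmembers|rightmembers` (comma-separated, universe order) and NA for
#' the unset sentinel. Round-trips bit-exactly through [readSdag()].
#'
#' @param d a [SubsplitDAG-class].
#' @param path output file path.
#' @export
writeSdag <- function(d, path) {
  ed <- d@edges
  lines <- c(paste0("#taxa\t", paste(d@taxa, collapse = ",")),
             paste(vapply(ed$parent, .subsplitLabel, "", taxa = d@taxa),
                   ed$which,
                   vapply(ed$child, .subsplitLabel, "", taxa = d@taxa),
                   ifelse(is.na(ed$length), "NA", sprintf("%.17g", ed$length)),
                   sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read an sDAG written by [writeSdag()]
#' @param path input file path.
#' @return a [SubsplitDAG-class].
#' @export
readSdag <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1L], "#taxa\t"))
    stop("missing #taxa header line")
  taxa <- strsplit(sub("^#taxa\t", "", lines[1L]), ",", fixed = TRUE)[[1]]
  body <- lines[-1L]
  body <- body[nzchar(body)]
  toKey <- function(label) {
    parts <- strsplit(label, "|", fixed = TRUE)[[1]]
    if (length(parts) == 1L) parts <- c(parts, "")
    bitsOf <- function(x) {
      members <- if (nzchar(x)) strsplit(x, ",", fixed = TRUE)[[1]] else character()
      unknown <- setdiff(members, taxa)
      if (length(unknown)) stop("unknown taxon label(s): ", paste(unknown, collapse = ", "))
      .cladeKey(taxa %in% members)
    }
    .subsplitKey(bitsOf(parts[1L]), bitsOf(parts[2L]))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 4L)
  if (length(bad)) stop("malformed edge line ", bad[1L] + 1L)
  ed <- data.frame(
    parent = vapply(fields, function(f) toKey(f[1L]), ""),
    which = vapply(fields, `[`, "", 2L),
    child = vapply(fields, function(f) toKey(f[3L]), ""),
    length = vapply(fields, function(f) suppressWarnings(as.numeric(f[4L])), 0),
    stringsAsFactors = FALSE)
  if (!all(ed$which %in% c("left", "right"))) stop("bad 'which' field")
  .newSdag(taxa, ed, validate = TRUE)
}
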