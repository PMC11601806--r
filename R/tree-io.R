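## Newick reading/writing for rooted bifurcating trees (ape "phylo" objects)
## and conversion between trees and their subsplit-DAG edge representation.

#' Parse a rooted bifurcating Newick string
#'
#' Wraps [ape::read.tree()] with strict validation: the tree must be rooted
#' (basal bifurcation), strictly bifurcating, with unique taxon labels. Missing
#' branch lengths default to 0. Internal node labels are ignored.
#'
#' @param s a Newick string (semicolon-terminated).
#' @param taxa optional taxon universe; when omitted it is inferred as the
#'   sorted tip labels. When given, tip labels must be a subset of it.
#' @return an [ape::phylo] object with an `edge.length` component and a
#'   `taxa` attribute recording the universe order.
#' @export
parseNewick <- function(s, taxa = NULL) {
  s <- trimws(s)
  depth <- 0L
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  quoted <- FALSE
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "'") quoted <- !quoted
    if (quoted) next
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop("unbalanced ')' at position ", i)
    }
  }
  if (depth != 0L) stop("unbalanced '(' (", depth, " unclosed) in Newick string")
  if (!grepl(";\\s*$", s)) stop("Newick string must end with ';'")
  phy <- ape::read.tree(text = s)
  if (is.null(phy)) stop("could not parse Newick string")
  if (inherits(phy, "multiPhylo")) stop("expected a single Newick tree")
  if (anyDuplicated(phy$tip.label))
    stop("duplicate taxa: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]), collapse = ", "))
  if (length(phy$tip.label) < 2L) stop("need at least 2 taxa")
  if (!ape::is.binary(phy) || !ape::is.rooted(phy)) {
    deg <- tabulate(phy$edge[, 1L])
    bad <- which(deg > 2L)
    stop("tree is not rooted and bifurcating (polytomy at internal node ",
         if (length(bad)) bad[1L] else "root", ")")
  }
  if (is.null(phy$edge.length)) phy$edge.length <- rep(0, nrow(phy$edge))
  phy$edge.length[is.na(phy$edge.length)] <- 0
  if (any(phy$edge.length < 0)) stop("negative branch length in Newick string")
  phy$node.label <- NULL
  if (is.null(taxa)) {
    taxa <- sort(phy$tip.label, method = "radix")
  } else {
    taxa <- as.character(taxa)
    missing <- setdiff(phy$tip.label, taxa)
    if (length(missing))
      stop("tip label(s) not in taxon universe: ", paste(missing, collapse = ", "))
  }
  attr(phy, "taxa") <- taxa
  phy
}

#' Taxon universe of a tree
#' @param phy a phylo object, possibly carrying a `taxa` attribute.
#' @return character vector of taxon labels in universe order.
#' @export
treeTaxa <- function(phy) {
  taxa <- attr(phy, "taxa")
  if (is.null(taxa)) taxa <- sort(phy$tip.label, method = "radix")
  taxa
}

## ---- internal: phylo -> subsplit edge table ("ttree") --------------------

## Returns a data.frame with columns parent, which, child (subsplit keys),
## length, key; one row per sDAG edge of the single-topology sDAG, including
## the rho -> root-split edge (length 0). 2n - 1 rows for n taxa.
.phyloToTtree <- function(phy, taxa = treeTaxa(phy)) {
  n <- length(phy$tip.label)
  if (!ape::is.binary(phy) || !ape::is.rooted(phy))
    stop("topology must be rooted and bifurcating")
  idx <- match(phy$tip.label, taxa)
  if (anyNA(idx)) stop("tip label(s) not in taxon universe")
  nt <- length(taxa)
  nNode <- n + phy$Nnode
  if (is.null(phy$edge.length)) phy$edge.length <- rep(0, nrow(phy$edge))
  ## leaf-set bits per phylo node, bottom-up
  bits <- matrix(FALSE, nNode, nt)
  bits[cbind(seq_len(n), idx)] <- TRUE
  po <- ape::reorder.phylo(phy, "postorder")
  for (r in seq_len(nrow(po$edge)))
    bits[po$edge[r, 1L], ] <- bits[po$edge[r, 1L], ] | bits[po$edge[r, 2L], ]
  ## subsplit key per phylo node
  childrenOf <- split(seq_len(nrow(phy$edge)), phy$edge[, 1L])
  nodeKey <- character(nNode)
  for (v in seq_len(n)) nodeKey[v] <- .leafKey(idx[v], nt)
  internal <- unique(phy$edge[, 1L])
  for (v in internal) {
    rows <- childrenOf[[as.character(v)]]
    k1 <- .cladeKey(bits[phy$edge[rows[1L], 2L], ])
    k2 <- .cladeKey(bits[phy$edge[rows[2L], 2L], ])
    if (.cladeSortKey(k1) <= .cladeSortKey(k2)) nodeKey[v] <- .subsplitKey(k1, k2)
    else nodeKey[v] <- .subsplitKey(k2, k1)
  }
  root <- n + 1L
  parent <- character(nrow(phy$edge) + 1L)
  which <- character(nrow(phy$edge) + 1L)
  child <- character(nrow(phy$edge) + 1L)
  len <- numeric(nrow(phy$edge) + 1L)
  for (r in seq_len(nrow(phy$edge))) {
    p <- phy$edge[r, 1L]; c <- phy$edge[r, 2L]
    parent[r] <- nodeKey[p]
    child[r] <- nodeKey[c]
    ck <- .cladeKey(bits[c, ])
    which[r] <- if (.sideKey(nodeKey[p], "left") == ck) "left" else "right"
    len[r] <- phy$edge.length[r]
  }
  r <- nrow(phy$edge) + 1L
  parent[r] <- .rhoKey(nt); which[r] <- "right"; child[r] <- nodeKey[root]; len[r] <- 0
  data.frame(parent = parent, which = which, child = child, length = len,
             key = .edgeKey(parent, which, child), stringsAsFactors = FALSE)
}

#' Subsplit-DAG edges of a rooted topology
#'
#' Every rooted bifurcating topology has a single-topology sDAG representation:
#' each node is labeled with the subsplit of the taxa leafward of it, and the
#' universal ancestor rho is attached above the root split. This returns its
#' `2n - 1` edges.
#'
#' @param phy a rooted bifurcating phylo object.
#' @param taxa optional taxon universe (default: inferred from the tree).
#' @return a data.frame with columns `parent`, `which`, `child` (subsplit
#'   keys), `length`, and `key`, sorted deterministically by edge order.
#' @export
topologyToEdges <- function(phy, taxa = treeTaxa(phy)) {
  tt <- .phyloToTtree(phy, taxa)
  tt[order(.edgeSortKey(tt$parent, tt$which, tt$child), method = "radix"), ,
     drop = FALSE]
}

## ---- internal: edge set -> newick / phylo --------------------------------

## edges: data.frame with parent/which/child/length. Must describe exactly one
## topology (each (node, clade) has exactly one outgoing edge).
.edgeSetToNewick <- function(edges, taxa, withLengths = TRUE, digits = 10L) {
  childOf <- new.env(parent = emptyenv(), hash = TRUE)
  for (r in seq_len(nrow(edges))) {
    slot <- paste(edges$parent[r], edges$which[r])
    if (!is.null(childOf[[slot]]))
      stop("edge set is not a single topology: two children at ", slot)
    childOf[[slot]] <- r
  }
  fmt <- function(x) sprintf(paste0("%.", digits, "g"), x)
  build <- function(key) {
    if (.isLeafKey(key)) return(taxa[.keyBits(.subsplitParts(key)[2L])])
    walk <- function(which) {
      r <- childOf[[paste(key, which)]]
      if (is.null(r)) stop("no child edge at (", .subsplitLabel(key, taxa), ", ", which, ")")
      sub <- build(edges$child[r])
      if (withLengths) paste0(sub, ":", fmt(edges$length[r])) else sub
    }
    paste0("(", walk("left"), ",", walk("right"), ")")
  }
  rootRow <- childOf[[paste(.rhoKey(length(taxa)), "right")]]
  if (is.null(rootRow)) stop("edge set has no root-split edge")
  paste0(build(edges$child[rootRow]), ";")
}

.edgeSetToPhylo <- function(edges, taxa, withLengths = TRUE) {
  phy <- ape::read.tree(text = .edgeSetToNewick(edges, taxa, withLengths))
  if (is.null(phy$edge.length)) phy$edge.length <- rep(0, nrow(phy$edge))
  attr(phy, "taxa") <- taxa
  phy
}

#' Write a tree as a canonical Newick string
#'
#' Children are ordered by the clade order of their leaf sets (so the writer is
#' a canonical form: two trees with the same topology and lengths produce
#' identical strings). Branch lengths are printed with 10 significant digits;
#' when all lengths are zero the `:length` suffixes are omitted.
#'
#' @param phy a rooted bifurcating phylo object.
#' @param taxa optional taxon universe.
#' @return a Newick string.
#' @export
writeNewick <- function(phy, taxa = treeTaxa(phy)) {
  tt <- .phyloToTtree(phy, taxa)
  .edgeSetToNewick(tt, taxa, withLengths = any(tt$length != 0))
}
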