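## Shared fixtures and independent oracles, built in code at test time.

taxa7 <- as.character(0:6)
taxa5 <- as.character(0:4)
taxa4 <- as.character(0:3)

## the two-tree seven-taxon union whose sDAG has two root-split options and
## two resolutions of the clade {4,5,6} (4 topologies total)
unionPairTrees <- function(withLengths = FALSE) {
  if (withLengths) list(
    parseNewick("(0:0.1,(1:0.1,(2:0.2,(3:0.1,(4:0.15,(5:0.1,6:0.1):0.1):0.1):0.2):0.1):0.1);", taxa7),
    parseNewick("((0:0.1,1:0.2):0.1,(2:0.1,(3:0.1,((4:0.1,6:0.1):0.1,5:0.1):0.1):0.1):0.1);", taxa7))
  else list(
    parseNewick("(0,(1,(2,(3,(4,(5,6))))));", taxa7),
    parseNewick("((0,1),(2,(3,((4,6),5))));", taxa7))
}

## the two-tree seven-taxon pair with a shared middle chain: differs in the
## placement of the root relative to taxon 6 and in the resolution of {3,4,5}
choicePairTrees <- function() list(
  parseNewick("(0:0.1,((1:0.1,(2:0.1,(3:0.1,(4:0.1,5:0.1):0.1):0.1):0.1):0.1,6:0.1):0.1);", taxa7),
  parseNewick("((0:0.1,(1:0.1,(2:0.1,((3:0.1,4:0.1):0.1,5:0.1):0.1):0.1):0.1):0.1,6:0.1);", taxa7))

## canonical topology string (lengths stripped)
topoKey <- function(phy, taxa = treeTaxa(phy)) {
  phy$edge.length <- NULL
  writeNewick(phy, taxa)
}

## all rooted bifurcating labeled topologies on a label set, as canonical
## topology-only newick strings (independent recursive enumeration)
allRootedTopologies <- function(labels) {
  rec <- function(lab) {
    if (length(lab) == 1L) return(lab)
    out <- character()
    rest <- lab[-1L]
    for (k in seq_len(length(rest))) {
      combs <- utils::combn(rest, k - 1L, simplify = FALSE)
      ## left part always contains lab[1] to count each split once
      for (cc in combs) {
        left <- c(lab[1L], cc)
        right <- setdiff(lab, left)
        if (!length(right)) next
        for (ls in rec(left)) for (rs in rec(right))
          out <- c(out, paste0("(", ls, ",", rs, ")"))
      }
    }
    out
  }
  unique(vapply(rec(labels), function(s)
    topoKey(parseNewick(paste0(s, ";"), sort(labels, method = "radix"))), ""))
}

## brute-force Felsenstein oracle: explicit sum over internal-node states
bruteTreeLogLik <- function(phy, aln) {
  m <- aln[phy$tip.label, , drop = FALSE]
  tt <- ape::reorder.phylo(phy, "postorder")
  n <- length(phy$tip.label)
  nNode <- n + phy$Nnode
  internals <- (n + 1L):nNode
  nuc <- c("A", "C", "G", "T")
  ll <- 0
  for (j in seq_len(ncol(m))) {
    tot <- 0
    for (assign in 0:(4^length(internals) - 1L)) {
      st <- integer(nNode)
      a <- assign
      for (ii in seq_along(internals)) {
        st[internals[ii]] <- a %% 4L + 1L
        a <- a %/% 4L
      }
      for (v in seq_len(n)) st[v] <- match(m[v, j], nuc)
      p <- 0.25
      for (r in seq_len(nrow(tt$edge))) {
        P <- jcTransitionMatrix(tt$edge.length[r])
        p <- p * P[st[tt$edge[r, 1L]], st[tt$edge[r, 2L]]]
      }
      tot <- tot + p
    }
    ll <- ll + log(tot)
  }
  ll
}

## independent rooted-NNI neighborhood of a topology: all topologies
## obtainable by swapping a subtree with its parent's sibling subtree,
## computed directly on the nested structure (no sDAG machinery)
nniNeighborTopologies <- function(phy) {
  taxa <- treeTaxa(phy)
  parse1 <- function(s) {
    ## minimal nested-list newick reader for topology-only strings
    s <- sub(";$", "", s)
    pos <- 1L
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    rd <- function() {
      if (chars[pos] == "(") {
        pos <<- pos + 1L
        l <- rd()
        stopifnot(chars[pos] == ",")
        pos <<- pos + 1L
        r <- rd()
        stopifnot(chars[pos] == ")")
        pos <<- pos + 1L
        return(list(l, r))
      }
      start <- pos
      while (pos <= length(chars) && !(chars[pos] %in% c(",", ")", "(")))
        pos <<- pos + 1L
      paste(chars[start:(pos - 1L)], collapse = "")
    }
    rd()
  }
  fmt <- function(node) if (!is.list(node)) node
    else paste0("(", fmt(node[[1L]]), ",", fmt(node[[2L]]), ")")
  out <- character()
  swapAt <- function(node) {
    ## node internal with children c1 c2; if ci internal, swap cj with a
    ## grandchild of ci
    if (!is.list(node)) return()
    for (i in 1:2) {
      ci <- node[[i]]; cj <- node[[3L - i]]
      if (is.list(ci)) {
        for (g in 1:2) {
          newCi <- ci
          newCi[[g]] <- cj
          newNode <- node
          newNode[[i]] <- newCi
          newNode[[3L - i]] <- ci[[g]]
          out <<- c(out, fmt(replaceIn(rootNested, node, newNode)))
        }
      }
    }
    if (is.list(node[[1L]])) swapAt(node[[1L]])
    if (is.list(node[[2L]])) swapAt(node[[2L]])
  }
  replaceIn <- function(tree, target, replacement) {
    if (identical(tree, target)) return(replacement)
    if (!is.list(tree)) return(tree)
    list(replaceIn(tree[[1L]], target, replacement),
         replaceIn(tree[[2L]], target, replacement))
  }
  rootNested <- parse1(topoKey(phy))
  swapAt(rootNested)
  unique(vapply(out, function(s)
    topoKey(parseNewick(paste0(s, ";"), taxa)), ""))
}

## small deterministic alignment on given taxa (hand-rolled, no simulation)
tinyAlignment <- function(taxa, sites) {
  stopifnot(nrow(sites) == length(taxa))
  rownames(sites) <- taxa
  sites
}
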