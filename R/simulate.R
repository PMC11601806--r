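## Fixture generation: random rooted topologies, JC sequence simulation, and
## the key=value configuration reader. All randomness is seed-driven and
## isolated from the caller's RNG state.

## run expr with a local RNG seeded by `seed` (NULL = use current stream)
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Uniformly random rooted bifurcating topology
#'
#' Sequential random attachment: taxa are added in order, each attached at a
#' uniformly chosen position among the current tree's `2k - 1` attachment
#' points (any edge, or above the root), which yields the uniform distribution
#' over the `(2n - 3)!!` rooted labeled bifurcating topologies.
#'
#' @param taxa integer (number of taxa, labeled "0".."n-1") or a character
#'   vector of labels; n >= 2.
#' @param seed optional integer seed for reproducibility.
#' @param brlenMean if nonzero, branch lengths are drawn Exponential with this
#'   mean (substitutions/site); 0 gives a topology with zero lengths.
#' @return a rooted bifurcating phylo object.
#' @export
randomRootedTopology <- function(taxa, seed = NULL, brlenMean = 0) {
  if (length(taxa) == 1L && is.numeric(taxa)) taxa <- as.character(seq_len(taxa) - 1L)
  taxa <- as.character(taxa)
  n <- length(taxa)
  if (n < 2L) stop("need at least 2 taxa")
  .withSeed(seed, {
    ## nested-list tree: a leaf is a label, an internal node a list of 2
    tree <- list(taxa[1L], taxa[2L])
    if (n > 2L) for (k in 3:n) {
      nNodes <- 2L * (k - 1L) - 1L
      target <- sample.int(nNodes, 1L)
      counter <- new.env(parent = emptyenv())
      counter$i <- 0L
      attach <- function(node) {
        counter$i <- counter$i + 1L
        if (counter$i == target) return(list(node, taxa[k]))
        if (!is.list(node)) return(node)
        node[[1L]] <- attach(node[[1L]])
        if (counter$i >= target) return(node)
        node[[2L]] <- attach(node[[2L]])
        node
      }
      tree <- attach(tree)
    }
    nwk <- function(node) if (!is.list(node)) node
      else paste0("(", nwk(node[[1L]]), ",", nwk(node[[2L]]), ")")
    phy <- parseNewick(paste0(nwk(tree), ";"), sort(taxa, method = "radix"))
    if (brlenMean > 0)
      phy$edge.length <- stats::rexp(nrow(phy$edge), rate = 1 / brlenMean)
    phy
  })
}

#' Simulate a Jukes-Cantor alignment down a tree
#'
#' Root states are i.i.d. uniform over A/C/G/T; states evolve independently
#' per site down each edge with [jcTransitionMatrix()].
#'
#' @param phy a rooted bifurcating phylo with all branch lengths assigned.
#' @param nSites number of alignment columns.
#' @param seed optional integer seed.
#' @return character matrix (taxa x sites) with taxon rownames.
#' @export
simulateJCAlignment <- function(phy, nSites, seed = NULL) {
  if (is.null(phy$edge.length) || anyNA(phy$edge.length))
    stop("tree has unset (sentinel) branch lengths")
  n <- length(phy$tip.label)
  nNode <- n + phy$Nnode
  .withSeed(seed, {
    states <- matrix(0L, nNode, nSites)
    states[n + 1L, ] <- sample.int(4L, nSites, replace = TRUE)
    ## preorder: parents before children
    pre <- ape::reorder.phylo(phy, "cladewise")
    for (r in seq_len(nrow(pre$edge))) {
      Pm <- jcTransitionMatrix(pre$edge.length[r])
      ps <- states[pre$edge[r, 1L], ]
      cs <- integer(nSites)
      for (s in 1:4) {
        w <- which(ps == s)
        if (length(w))
          cs[w] <- sample.int(4L, length(w), replace = TRUE, prob = Pm[s, ])
      }
      states[pre$edge[r, 2L], ] <- cs
    }
    m <- matrix(.NUC[states[seq_len(n), ]], n, nSites)
    rownames(m) <- phy$tip.label
    m
  })
}

#' Write an alignment matrix to FASTA
#' @param aln character matrix with taxon rownames.
#' @param path output path.
#' @export
writeFastaAlignment <- function(aln, path) {
  m <- .asAlignmentMatrix(aln)
  seqs <- Biostrings::DNAStringSet(apply(m, 1L, paste, collapse = ""))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a key=value configuration file
#'
#' Lines of the form `key = value`; blank lines and `#` comments ignored.
#' Values that parse as numbers become numeric. Unknown keys are kept, so the
#' result can be merged over [sdagConfig()] defaults.
#'
#' @param path configuration file path.
#' @return a named list.
#' @export
readSdagConfig <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("malformed config line: ", ln)
    key <- trimws(kv[1L]); val <- trimws(kv[2L])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

#' Default tunable parameters for likelihoods and searches
#'
#' @param ... overrides of the defaults: `brlenLower`, `brlenUpper` (Brent
#'   bounds, substitutions/site), `brlenTol` (absolute convergence tolerance),
#'   `maxSweeps` (coordinate sweeps), `newEdgeInit` (initial length for edges
#'   with no pre-NNI counterpart), `enumerationCap` (brute-force enumeration
#'   guard), `optimizeAllNewEdges` (top pruning: also optimize non-central new
#'   edges inside the NNI evaluation).
#' @return a named list of parameters.
#' @export
sdagConfig <- function(...) {
  cfg <- list(brlenLower = 1e-6, brlenUpper = 10, brlenTol = 1e-4,
              maxSweeps = 5L, newEdgeInit = 0.1, enumerationCap = 1e5,
              optimizeAllNewEdges = FALSE)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  cfg
}
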