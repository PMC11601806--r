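## Jukes-Cantor substitution model, Felsenstein pruning on a single tree, and
## coordinate-wise Brent branch-length optimization.

.NUC <- c("A", "C", "G", "T")

## IUPAC ambiguity -> 4-row indicator columns; gaps and unknowns are fully
## ambiguous (all-ones), the standard Felsenstein convention.
.IUPAC <- local({
  codes <- list(A = "A", C = "C", G = "G", T = "T", U = "T",
                R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                B = c("C", "G", "T"), D = c("A", "G", "T"),
                H = c("A", "C", "T"), V = c("A", "C", "G"),
                N = c("A", "C", "G", "T"), "-" = c("A", "C", "G", "T"),
                "?" = c("A", "C", "G", "T"), "." = c("A", "C", "G", "T"))
  m <- sapply(codes, function(x) as.numeric(.NUC %in% x))
  rownames(m) <- .NUC
  m
})

#' Jukes-Cantor transition probability matrix
#'
#' @param t branch length in expected substitutions per site (t >= 0).
#' @return 4x4 row-stochastic matrix with diagonal
#'   `1/4 + (3/4) exp(-4t/3)` and off-diagonal `1/4 - (1/4) exp(-4t/3)`.
#' @examples
#' jcTransitionMatrix(0)    # identity
#' jcTransitionMatrix(1e6)  # ~ all 1/4
#' @export
jcTransitionMatrix <- function(t) {
  if (!is.finite(t) && !identical(t, Inf)) stop("branch length must be numeric")
  if (t < 0) stop("branch length must be nonnegative, got ", t)
  e <- exp(-4 * t / 3)
  m <- matrix(0.25 - 0.25 * e, 4, 4, dimnames = list(.NUC, .NUC))
  diag(m) <- 0.25 + 0.75 * e
  m
}

## ---- alignment handling --------------------------------------------------

#' Read a DNA multiple sequence alignment from FASTA
#'
#' Case-insensitive; IUPAC ambiguity codes and gaps are accepted (scored as
#' fully ambiguous). Sequences must have equal lengths.
#'
#' @param path path to a FASTA file.
#' @return a character matrix (taxa in rows, sites in columns) with taxon
#'   names as rownames.
#' @export
readFastaAlignment <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (!length(seqs)) stop("empty FASTA file: ", path)
  widths <- Biostrings::width(seqs)
  if (length(unique(widths)) != 1L)
    stop("sequences have unequal lengths; not an alignment")
  m <- do.call(rbind, strsplit(toupper(as.character(seqs)), "", fixed = TRUE))
  rownames(m) <- names(seqs)
  m
}

## normalize any supported alignment input to a character matrix
.asAlignmentMatrix <- function(aln) {
  if (inherits(aln, "DNAStringSet")) {
    m <- do.call(rbind, strsplit(toupper(as.character(aln)), "", fixed = TRUE))
    rownames(m) <- names(aln)
    return(m)
  }
  if (is.matrix(aln) && is.character(aln)) {
    m <- toupper(aln)
    return(m)
  }
  if (is.character(aln) && !is.null(names(aln))) {
    m <- do.call(rbind, strsplit(toupper(aln), "", fixed = TRUE))
    rownames(m) <- names(aln)
    return(m)
  }
  stop("unsupported alignment representation")
}

## Pattern-compressed alignment: per-taxon 4 x P indicator matrices, pattern
## weights, total site count. Shared by single-tree and sDAG likelihoods.
.compressAlignment <- function(aln, taxa) {
  m <- .asAlignmentMatrix(aln)
  if (is.null(rownames(m))) stop("alignment has no taxon names")
  missing <- setdiff(taxa, rownames(m))
  if (length(missing))
    stop("alignment is missing taxa: ", paste(missing, collapse = ", "))
  m <- m[taxa, , drop = FALSE]
  bad <- setdiff(unique(as.vector(m)), colnames(.IUPAC))
  if (length(bad)) stop("unrecognized residue(s): ", paste(bad, collapse = ", "))
  pat <- apply(m, 2L, paste, collapse = "\r")
  tab <- table(factor(pat, levels = unique(pat)))
  keep <- match(names(tab), pat)
  partials <- lapply(seq_along(taxa), function(i)
    .IUPAC[, m[i, keep], drop = FALSE])
  names(partials) <- taxa
  list(partials = partials, weights = as.numeric(tab),
       nPatterns = length(keep), nSites = ncol(m), taxa = taxa)
}

## ---- Felsenstein pruning -------------------------------------------------

## Per-pattern log site likelihoods for one tree; caln from .compressAlignment.
## Returns numeric vector length nPatterns.
.treeSiteLogLik <- function(phy, caln) {
  if (is.null(phy$edge.length) || anyNA(phy$edge.length))
    stop("tree has unset (sentinel) branch lengths")
  n <- length(phy$tip.label)
  if (!all(phy$tip.label %in% caln$taxa))
    stop("tree taxa do not match the alignment")
  po <- ape::reorder.phylo(phy, "postorder")
  nNode <- n + phy$Nnode
  P <- caln$nPatterns
  plv <- vector("list", nNode)
  scale <- matrix(0, nNode, P)
  for (v in seq_len(n)) plv[[v]] <- caln$partials[[phy$tip.label[v]]]
  prev <- vector("list", nNode)
  for (r in seq_len(nrow(po$edge))) {
    p <- po$edge[r, 1L]; c <- po$edge[r, 2L]
    contrib <- jcTransitionMatrix(po$edge.length[r]) %*% plv[[c]]
    if (is.null(prev[[p]])) {
      plv[[p]] <- contrib
      scale[p, ] <- scale[c, ]
      prev[[p]] <- TRUE
    } else {
      plv[[p]] <- plv[[p]] * contrib
      scale[p, ] <- scale[p, ] + scale[c, ]
      mx <- apply(plv[[p]], 2L, max)
      pos <- mx > 0
      plv[[p]][, pos] <- plv[[p]][, pos, drop = FALSE] /
        rep(mx[pos], each = 4L)
      scale[p, pos] <- scale[p, pos] + log(mx[pos])
    }
  }
  root <- n + 1L
  log(colSums(plv[[root]] * 0.25)) + scale[root, ]
}

#' Felsenstein log likelihood of a tree under Jukes-Cantor
#'
#' Computes `sum_i log p(Y_i | tree)` by the pruning algorithm with stationary
#' root frequencies 1/4 and per-node scaling against underflow. Identical
#' alignment columns are compressed into patterns.
#'
#' @param phy a rooted bifurcating phylo object with all branch lengths
#'   assigned (NA lengths raise an error).
#' @param aln an alignment: character matrix with taxa as rownames, a named
#'   character vector of sequences, or a `DNAStringSet`.
#' @return the log likelihood (a scalar).
#' @export
treeLogLikelihood <- function(phy, aln) {
  caln <- if (is.list(aln) && !is.null(aln$partials)) aln
          else .compressAlignment(aln, sort(phy$tip.label, method = "radix"))
  sum(.treeSiteLogLik(phy, caln) * caln$weights)
}

## ---- coordinate-wise Brent optimization ----------------------------------

#' Coordinate-ascent branch-length optimization with Brent line search
#'
#' Takes one coordinate at a time, holds the others fixed, maximizes with
#' Brent's method ([stats::optimize()]), and sweeps in the given order until
#' the largest absolute per-sweep change drops below `tol` or `maxSweeps` is
#' reached. The objective never decreases between sweeps.
#'
#' @param objective function taking the full numeric length vector, returning
#'   a finite objective value (larger is better).
#' @param init numeric vector of starting lengths.
#' @param lower,upper Brent search bounds per coordinate (substitutions/site).
#' @param tol absolute convergence tolerance on length changes per sweep.
#' @param maxSweeps maximum number of coordinate sweeps.
#' @return the optimized numeric length vector, with attribute `objective`.
#' @export
optimizeBranchLengths <- function(objective, init, lower = 1e-6, upper = 10,
                                  tol = 1e-4, maxSweeps = 5L) {
  x <- pmin(pmax(as.numeric(init), lower), upper)
  f0 <- objective(x)
  if (!is.finite(f0)) stop("objective is not finite at the initial lengths")
  for (sweep in seq_len(maxSweeps)) {
    maxDelta <- 0
    for (i in seq_along(x)) {
      fi <- function(v) {
        y <- x; y[i] <- v
        val <- objective(y)
        if (is.nan(val)) stop("objective is not finite while optimizing edge ", i)
        val
      }
      opt <- stats::optimize(fi, lower = lower, upper = upper, maximum = TRUE,
                             tol = min(tol, 1e-4))
      ## Brent can return an interior point slightly worse than the incumbent
      ## or the boundary; keep the best of candidate, current, and bounds
      cand <- c(opt$maximum, x[i], lower)
      vals <- c(opt$objective, fi(x[i]), fi(lower))
      best <- which.max(vals)
      maxDelta <- max(maxDelta, abs(cand[best] - x[i]))
      x[i] <- cand[best]
    }
    if (maxDelta < tol) break
  }
  attr(x, "objective") <- objective(x)
  x
}
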