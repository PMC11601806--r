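## Core subsplit algebra: taxon sets, clades, subsplits, their total order and
## parent/child compatibility. Everything else in the package is built on the
## string-key representation defined here: a clade is a membership bitstring
## over the (fixed) taxon order, a subsplit is "leftbits|rightbits".

#' Clade of a fixed taxon set
#'
#' A clade is a subset of an ordered taxon universe, stored as a membership
#' vector. The taxon order is fixed for the lifetime of every structure built
#' on it and induces a total order on clades (see [compareClades()]).
#'
#' @slot taxa character vector of distinct taxon labels, in universe order.
#' @slot members logical membership vector, parallel to `taxa`.
#' @export
setClass("Clade", representation(taxa = "character", members = "logical"),
         validity = function(object) {
           if (anyDuplicated(object@taxa)) return("duplicate taxon labels")
           if (length(object@taxa) != length(object@members))
             return("members must be parallel to taxa")
           TRUE
         })

#' Subsplit: an ordered pair of disjoint clades
#'
#' A subsplit is a bipartition of a subset of the taxon set into two disjoint
#' clades, the node label of the subsplit DAG. The lesser clade under the clade
#' order is stored on the left. Degenerate subsplits have an empty left clade:
#' leaf subsplits pair the empty clade with a singleton, and the universal
#' ancestor (rho) pairs the empty clade with the full taxon set.
#'
#' @slot taxa character, the taxon universe in order.
#' @slot left,right logical membership vectors of the two clades.
#' @export
setClass("Subsplit",
         representation(taxa = "character", left = "logical", right = "logical"),
         validity = function(object) {
           if (any(object@left & object@right)) return("clades overlap")
           if (!any(object@left | object@right)) return("both clades empty")
           TRUE
         })

## ---- internal key helpers ------------------------------------------------

.cladeKey <- function(members) paste(as.integer(members), collapse = "")

.keyBits <- function(key) strsplit(key, "", fixed = TRUE)[[1]] == "1"

.emptyKey <- function(n) strrep("0", n)

.fullKey <- function(n) strrep("1", n)

## Sort key realizing the clade total order as plain string order: the empty
## clade is the unique minimum; among nonempty clades the taxon with smaller
## index wins ("member sorts before non-member"), i.e. bit-inverted
## lexicographic order.
.cladeSortKey <- function(key) {
  out <- chartr("01", "10", key)
  out[grepl("^0*$", key)] <- ""
  out
}

.subsplitKey <- function(leftKey, rightKey) paste(leftKey, rightKey, sep = "|")

.subsplitParts <- function(key) {
  parts <- strsplit(key, "|", fixed = TRUE)[[1]]
  if (length(parts) == 1L) parts <- c(parts, "")
  parts
}

.subsplitSortKey <- function(key) {
  n <- nchar(key)
  left <- substr(key, 1L, (n - 1L) %/% 2L)
  right <- substr(key, (n - 1L) %/% 2L + 2L, n)
  paste(.cladeSortKey(left), .cladeSortKey(right), sep = ",")
}

## union of the two clades of a subsplit key, as a clade key
.subsplitUnion <- function(key) {
  parts <- .subsplitParts(key)
  .cladeKey(.keyBits(parts[1L]) | .keyBits(parts[2L]))
}

.rhoKey <- function(n) .subsplitKey(.emptyKey(n), .fullKey(n))

.leafKey <- function(i, n) {
  bits <- rep(FALSE, n)
  bits[i] <- TRUE
  .subsplitKey(.emptyKey(n), .cladeKey(bits))
}

.isLeafKey <- function(key) {
  parts <- .subsplitParts(key)
  grepl("^0*$", parts[1L]) && sum(.keyBits(parts[2L])) == 1L
}

.isRhoKey <- function(key) {
  parts <- .subsplitParts(key)
  grepl("^0*$", parts[1L]) && grepl("^1*$", parts[2L])
}

## clade key of one side of a subsplit key
.sideKey <- function(key, which) {
  parts <- .subsplitParts(key)
  parts[if (which == "left") 1L else 2L]
}

.otherSide <- function(which) if (which == "left") "right" else "left"

## human-readable label, e.g. "2|3,4,5"
.subsplitLabel <- function(key, taxa) {
  parts <- .subsplitParts(key)
  lab <- function(k) paste(taxa[.keyBits(k)], collapse = ",")
  paste(lab(parts[1L]), lab(parts[2L]), sep = "|")
}

.edgeKey <- function(parent, which, child) paste(parent, which, child)

.edgeSortKey <- function(parent, which, child) {
  paste(.subsplitSortKey(parent), which, .subsplitSortKey(child))
}

## ---- exported operations -------------------------------------------------

#' Construct a clade
#'
#' @param labels character vector of taxon labels (possibly empty).
#' @param taxa the taxon universe, an ordered character vector of unique labels.
#' @return a [Clade-class] object.
#' @examples
#' makeClade(c("4", "5", "6"), as.character(0:6))
#' @export
makeClade <- function(labels, taxa) {
  labels <- as.character(labels)
  if (anyDuplicated(taxa)) stop("taxon universe contains duplicate labels")
  if (anyDuplicated(labels))
    stop("duplicate clade labels: ", paste(unique(labels[duplicated(labels)]), collapse = ", "))
  unknown <- setdiff(labels, taxa)
  if (length(unknown))
    stop("unknown taxon label(s): ", paste(unknown, collapse = ", "))
  new("Clade", taxa = taxa, members = taxa %in% labels)
}

#' Compare two clades under the package's total order
#'
#' The order extends the taxon order: the empty clade precedes every nonempty
#' clade, and between nonempty clades the one containing the earlier taxon at
#' the first point of difference is the lesser.
#'
#' @param a,b [Clade-class] objects over the same taxon universe.
#' @return one of `"LT"`, `"EQ"`, `"GT"`.
#' @export
compareClades <- function(a, b) {
  if (!identical(a@taxa, b@taxa)) stop("clades are over different taxon universes")
  ka <- .cladeSortKey(.cladeKey(a@members))
  kb <- .cladeSortKey(.cladeKey(b@members))
  if (ka == kb) "EQ" else if (ka < kb) "LT" else "GT"
}

#' Construct a subsplit from two disjoint clades
#'
#' The result is canonically ordered (lesser clade on the left), so the two
#' argument orders give identical objects.
#'
#' @param a,b disjoint [Clade-class] objects over the same universe.
#' @return a [Subsplit-class] object.
#' @examples
#' taxa <- as.character(0:6)
#' makeSubsplit(makeClade("4", taxa), makeClade(c("5", "6"), taxa))
#' @export
makeSubsplit <- function(a, b) {
  if (!identical(a@taxa, b@taxa)) stop("clades are over different taxon universes")
  overlap <- a@members & b@members
  if (any(overlap))
    stop("clades overlap on: ", paste(a@taxa[overlap], collapse = ", "))
  if (!any(a@members | b@members)) stop("both clades are empty")
  if (compareClades(a, b) == "GT") {
    tmp <- a; a <- b; b <- tmp
  }
  new("Subsplit", taxa = a@taxa, left = a@members, right = b@members)
}

#' Parent-child subsplit compatibility
#'
#' An edge of the subsplit DAG connects a parent subsplit `t` to a child
#' subsplit `s` through one of `t`'s clades: the edge is valid precisely when
#' the union of `s`'s two clades equals the designated clade of `t`.
#'
#' @param parent,child [Subsplit-class] objects over the same universe.
#' @param which `"left"` or `"right"`: which clade of `parent` is partitioned.
#' @return logical. Degenerate queries (an empty designated clade) return FALSE.
#' @export
isValidChild <- function(parent, which, child) {
  which <- match.arg(which, c("left", "right"))
  if (!identical(parent@taxa, child@taxa))
    stop("subsplits are over different taxon universes")
  target <- if (which == "left") parent@left else parent@right
  if (!any(target)) return(FALSE)
  ## a child with an empty clade must be a leaf subsplit (empty clades occur
  ## only in rho and leaves); in particular rho can never be a child
  if ((!any(child@left) || !any(child@right)) && sum(child@left | child@right) != 1L)
    return(FALSE)
  identical(target, child@left | child@right)
}

#' @describeIn makeSubsplit construct a subsplit from a "left|right" label
#'   string with comma-separated taxon labels, e.g. `"2|3,4,5"`.
#' @param label character scalar, `"leftmembers|rightmembers"`.
#' @param taxa the taxon universe.
#' @export
parseSubsplit <- function(label, taxa) {
  parts <- strsplit(label, "|", fixed = TRUE)[[1]]
  if (length(parts) > 2L) stop("malformed subsplit label: ", label)
  if (length(parts) == 1L) parts <- c(parts, "")
  splitLabels <- function(x) if (nzchar(x)) strsplit(x, ",", fixed = TRUE)[[1]] else character()
  makeSubsplit(makeClade(splitLabels(parts[1L]), taxa),
               makeClade(splitLabels(parts[2L]), taxa))
}

#' Format a subsplit as a "left|right" label string
#' @param s a [Subsplit-class] object.
#' @return character scalar such as `"2|3,4,5"`.
#' @export
formatSubsplit <- function(s) {
  .subsplitLabel(.subsplitKey(.cladeKey(s@left), .cladeKey(s@right)), s@taxa)
}

## internal: Subsplit object <-> key
.ssKey <- function(s) .subsplitKey(.cladeKey(s@left), .cladeKey(s@right))

.keyToSubsplit <- function(key, taxa) {
  parts <- .subsplitParts(key)
  new("Subsplit", taxa = taxa, left = .keyBits(parts[1L]), right = .keyBits(parts[2L]))
}

## key-level validity check used in hot paths (same predicate as isValidChild)
.keyValidChild <- function(parentKey, which, childKey) {
  target <- .sideKey(parentKey, which)
  if (grepl("^0*$", target)) return(FALSE)
  parts <- .subsplitParts(childKey)
  degenerate <- grepl("^0*$", parts[1L]) || grepl("^0*$", parts[2L])
  if (degenerate && !.isLeafKey(childKey)) return(FALSE)
  .subsplitUnion(childKey) == target
}

setMethod("show", "Clade", function(object) {
  cat("Clade {", paste(object@taxa[object@members], collapse = ","),
      "} of ", length(object@taxa), " taxa\n", sep = "")
})

setMethod("show", "Subsplit", function(object) {
  cat("Subsplit {{", paste(object@taxa[object@left], collapse = ","), "},{",
      paste(object@taxa[object@right], collapse = ","), "}}\n", sep = "")
})
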