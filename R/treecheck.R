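## Distance-tree verification that labelled syngens are monophyletic, with
## column-bootstrap support. A desk-scale check of clade recovery; model
## selection, ML and parsimony analyses are deliberately out of scope.

#' Concatenate marker alignments column-wise
#'
#' Records are matched by id (every alignment must contain the same id
#' set).  Per-marker column provenance is attached as attribute
#' \code{"provenance"} (a data.frame with \code{marker}, \code{from},
#' \code{to} in concatenated 1-based coordinates).
#'
#' @param alns List of [MarkerAlignment-class] objects.
#' @return A [MarkerAlignment-class] with marker \code{"concat"}.
#' @export
concatenateAlignments <- function(alns) {
  stopifnot(length(alns) >= 1L)
  ids <- recordIds(alns[[1]])
  for (a in alns[-1])
    if (!setequal(recordIds(a), ids))
      stop("alignments do not share the same record ids")
  seqs <- rep("", length(ids))
  prov <- list(); at <- 0L
  for (a in alns) {
    seqs <- paste0(seqs, sequences(a)[ids])
    prov[[length(prov) + 1L]] <- data.frame(
      marker = markerName(a), from = at + 1L,
      to = at + alignmentLength(a))
    at <- at + alignmentLength(a)
  }
  out <- new("MarkerAlignment", marker = "concat", ids = ids, seqs = seqs,
             desc = character(length(ids)))
  attr(out, "provenance") <- do.call(rbind, prov)
  out
}

#' Pairwise p-distance matrix
#'
#' Fraction of differing sites over the columns non-missing in both
#' members of each pair (gaps and ambiguity codes are missing).
#'
#' @param aln A [MarkerAlignment-class] (possibly concatenated).
#' @return A symmetric numeric matrix with zero diagonal, dimnames = record
#'   ids.
#' @export
pDistance <- function(aln) {
  stopifnot(is(aln, "MarkerAlignment"))
  if (length(aln) < 3L) stop("need at least 3 records")
  m <- seqMatrix(aln)
  miss <- matrix(.isMissingState(m, aln@marker), nrow = nrow(m))
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(aln@ids, aln@ids))
  for (i in seq_len(n - 1L)) for (k in (i + 1L):n) {
    ok <- !miss[i, ] & !miss[k, ]
    if (!any(ok))
      stop(sprintf("records '%s' and '%s' share no non-missing column",
                   aln@ids[i], aln@ids[k]))
    d[i, k] <- d[k, i] <- mean(m[i, ok] != m[k, ok])
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ agglomeration (via \pkg{ape}); negative branch lengths are
#' clamped to zero with a message.
#'
#' @param D Symmetric distance matrix with dimnames.
#' @return An unrooted \code{phylo} tree.
#' @export
neighborJoining <- function(D) {
  if (nrow(D) < 3L) stop("need at least 3 taxa")
  tr <- ape::nj(stats::as.dist(D))
  neg <- tr$edge.length < 0
  if (any(neg)) {
    message(sprintf("neighborJoining: clamped %d negative branch length(s) to 0",
                    sum(neg)))
    tr$edge.length[neg] <- 0
  }
  tr
}

## all non-trivial leaf bipartitions of an unrooted tree, as leaf-label sets
## (one side each)
.treeSplits <- function(tree) {
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  lapply(pp, function(ix) labs[ix])
}

#' Check labelled clades for monophyly
#'
#' A clade is monophyletic when some edge bipartition of the tree separates
#' exactly its members from all other labelled leaves; leaves labelled
#' \code{"UNKNOWN"} (or absent from the partition) are ignored on both
#' sides.  Single-member clades are trivially monophyletic.
#'
#' @param tree A \code{phylo} tree.
#' @param partition A [CladePartition-class]; every labelled id must be a
#'   leaf of the tree.
#' @return A data.frame with columns \code{clade} and \code{monophyletic}.
#' @export
checkMonophyly <- function(tree, partition) {
  stopifnot(inherits(tree, "phylo"), is(partition, "CladePartition"))
  cl <- cladeOf(partition)
  labelledIds <- names(cl)[cl != "UNKNOWN"]
  missing <- setdiff(labelledIds, tree$tip.label)
  if (length(missing))
    stop("labelled id(s) missing from tree: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  labelledTips <- intersect(tree$tip.label, labelledIds)
  splits <- c(.treeSplits(tree), as.list(tree$tip.label))
  splitSets <- lapply(splits, function(s) sort(intersect(s, labelledTips)))
  compSets <- lapply(splits, function(s)
    sort(setdiff(labelledTips, s)))
  clades <- cladeLevels(partition)
  mono <- vapply(clades, function(cc) {
    mem <- sort(names(cl)[cl == cc])
    if (length(mem) <= 1L || length(mem) == length(labelledTips))
      return(TRUE)
    any(vapply(splitSets, identical, logical(1), mem)) ||
      any(vapply(compSets, identical, logical(1), mem))
  }, logical(1))
  data.frame(clade = clades, monophyletic = unname(mono))
}

#' Column-bootstrap support for clade monophyly
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree and
#' reports, per clade, the fraction of replicates in which it is
#' monophyletic.  Seeded and reproducible; the caller's random-number
#' state is restored on exit.
#'
#' @param aln A [MarkerAlignment-class] (possibly concatenated).
#' @param partition A [CladePartition-class].
#' @param nReps Number of bootstrap replicates (>= 1).
#' @param seed Integer seed.
#' @return A data.frame with columns \code{clade} and \code{support}.
#' @export
bootstrapSupport <- function(aln, partition, nReps = 100L, seed = 1L) {
  stopifnot(nReps >= 1L)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  m <- seqMatrix(aln)
  clades <- cladeLevels(partition)
  hits <- stats::setNames(numeric(length(clades)), clades)
  for (r in seq_len(nReps)) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    boot <- new("MarkerAlignment", marker = aln@marker, ids = aln@ids,
                seqs = apply(m[, cols, drop = FALSE], 1L, paste,
                             collapse = ""),
                desc = aln@desc)
    res <- checkMonophyly(suppressMessages(neighborJoining(pDistance(boot))),
                          partition)
    hits[res$clade] <- hits[res$clade] + res$monophyletic
  }
  data.frame(clade = clades, support = unname(hits[clades]) / nReps)
}
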