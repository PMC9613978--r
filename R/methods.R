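## Accessor and show methods for the package classes.

#' @rdname accessors
#' @aliases markerName,MarkerAlignment-method
setMethod("markerName", "MarkerAlignment", function(x, ...) x@marker)

#' @rdname accessors
setMethod("recordIds", "MarkerAlignment", function(x, ...) x@ids)

#' @rdname accessors
setMethod("sequences", "MarkerAlignment", function(x, ...) {
  stats::setNames(x@seqs, x@ids)
})

#' @rdname accessors
setMethod("alignmentLength", "MarkerAlignment", function(x, ...) {
  nchar(x@seqs[1L])
})

#' @describeIn accessors Character matrix (records x columns) of an
#'   alignment; rownames are record ids.
setMethod("seqMatrix", "MarkerAlignment", function(x, ...) {
  m <- do.call(rbind, strsplit(x@seqs, ""))
  rownames(m) <- x@ids
  m
})

#' Number of records in an alignment
#' @param x A [MarkerAlignment-class].
#' @export
setMethod("length", "MarkerAlignment", function(x) length(x@ids))

#' Subset an alignment by records and/or columns
#'
#' @param x A [MarkerAlignment-class].
#' @param i Record selector (indices, logical, or ids).
#' @param j Optional 1-based column selector.
#' @param ... Ignored.
#' @param drop Ignored.
#' @return A [MarkerAlignment-class].
#' @export
setMethod("[", "MarkerAlignment", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_along(x@ids)
  if (is.character(i)) i <- match(i, x@ids)
  if (anyNA(i)) stop("unknown record id in subset")
  seqs <- x@seqs[i]
  if (!missing(j)) {
    mat <- do.call(rbind, strsplit(seqs, ""))
    seqs <- apply(mat[, j, drop = FALSE], 1L, paste, collapse = "")
  }
  new("MarkerAlignment", marker = x@marker, ids = x@ids[i], seqs = seqs,
      desc = x@desc[i])
})

setMethod("show", "MarkerAlignment", function(object) {
  cat(sprintf("MarkerAlignment [%s]: %d records x %d columns\n",
              object@marker, length(object@ids),
              alignmentLength(object)))
  n <- min(3L, length(object@ids))
  for (i in seq_len(n)) {
    s <- object@seqs[i]
    cat(sprintf("  %-15s %s%s\n", object@ids[i],
                substr(s, 1L, 40L), if (nchar(s) > 40L) "..." else ""))
  }
  if (length(object@ids) > n) cat(sprintf("  ... and %d more\n",
                                          length(object@ids) - n))
})

#' @rdname accessors
setMethod("cladeOf", "CladePartition", function(x, ...) {
  stats::setNames(x@clade, x@ids)
})

#' @describeIn accessors Distinct labelled (non-UNKNOWN) clade labels of a
#'   partition, in syngen order where applicable.
setMethod("cladeLevels", "CladePartition", function(x, ...) {
  lv <- unique(x@clade[x@clade != "UNKNOWN"])
  known <- intersect(syngenLevels(), lv)
  c(known, sort(setdiff(lv, known)))
})

#' Number of records in a partition
#' @param x A [CladePartition-class].
#' @export
setMethod("length", "CladePartition", function(x) length(x@ids))

setMethod("show", "CladePartition", function(object) {
  tab <- table(factor(object@clade))
  cat(sprintf("CladePartition: %d records in %d labelled clade(s)\n",
              length(object@ids), length(cladeLevels(object))))
  print(tab)
})

#' Number of variable columns profiled
#' @param x A [ColumnProfileSet-class].
#' @export
setMethod("length", "ColumnProfileSet", function(x) length(x@columns))

setMethod("show", "ColumnProfileSet", function(object) {
  cat(sprintf("ColumnProfileSet [%s]: %d variable column(s) of %d record(s) (policy: %s)\n",
              object@marker, length(object@columns), object@nRecords,
              object@policy))
  if (length(object@columns))
    cat("  columns:", paste(utils::head(object@columns, 15L), collapse = ", "),
        if (length(object@columns) > 15L) "..." else "", "\n")
})

#' @rdname accessors
setMethod("markerName", "ColumnProfileSet", function(x, ...) x@marker)

#' @rdname accessors
setMethod("markerName", "SignatureSet", function(x, ...) x@marker)

#' @rdname accessors
setMethod("signatureEntries", "SignatureSet", function(x, ...) x@entries)

#' @rdname accessors
setMethod("signatureEntries", "CombinedSignature", function(x, ...) x@entries)

#' @rdname accessors
setMethod("cladeLevels", "SignatureSet", function(x, ...) x@clades)

#' @rdname accessors
setMethod("cladeLevels", "CombinedSignature", function(x, ...) x@clades)

#' @rdname accessors
setMethod("separability", "CombinedSignature", function(x, ...) x@separability)

.triplesFromEntries <- function(entries, clades) {
  out <- list()
  syn <- entries[entries$category == "SYNAPOMORPHY", , drop = FALSE]
  for (k in seq_len(nrow(syn))) {
    dg <- strsplit(syn$diagnostic_for[k], ",", fixed = TRUE)[[1]]
    for (cl in dg) {
      out[[length(out) + 1L]] <- data.frame(
        marker = syn$marker[k], column = syn$column[k], clade = cl,
        state = syn[[paste0("state_", cl)]][k],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(marker = character(), column = integer(),
                      clade = character(), state = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' @rdname diagnosticTriples
setMethod("diagnosticTriples", "SignatureSet", function(x) {
  e <- cbind(data.frame(marker = rep(x@marker, nrow(x@entries)),
                        stringsAsFactors = FALSE),
             x@entries)
  .triplesFromEntries(e, x@clades)
})

#' @rdname diagnosticTriples
setMethod("diagnosticTriples", "CombinedSignature", function(x) {
  .triplesFromEntries(x@entries, x@clades)
})

setMethod("show", "SignatureSet", function(object) {
  tab <- table(factor(object@entries$category, levels = .SIG_CATEGORIES))
  cat(sprintf("SignatureSet [%s]: %d variable column(s)\n", object@marker,
              nrow(object@entries)))
  cat(sprintf("  SYNAPOMORPHY: %d, WITHIN_CLADE_VARIABLE: %d, OTHER_VARIABLE: %d\n",
              tab[["SYNAPOMORPHY"]], tab[["WITHIN_CLADE_VARIABLE"]],
              tab[["OTHER_VARIABLE"]]))
})

setMethod("show", "CombinedSignature", function(object) {
  cat(sprintf("CombinedSignature: %d entr%s over marker(s) %s\n",
              nrow(object@entries),
              if (nrow(object@entries) == 1L) "y" else "ies",
              paste(unique(object@entries$marker), collapse = ", ")))
  print(object@separability)
})

#' @rdname accessors
setMethod("markerName", "HaplotypeSet", function(x, ...) x@marker)

#' @rdname accessors
setMethod("hapIds", "HaplotypeSet", function(x, ...) x@hapIds)

#' @describeIn accessors Haplotype frequencies (member counts).
setMethod("hapFreq", "HaplotypeSet", function(x, ...) {
  stats::setNames(lengths(x@members), x@hapIds)
})

#' @rdname accessors
setMethod("hapMembers", "HaplotypeSet", function(x, ...) {
  stats::setNames(x@members, x@hapIds)
})

#' @rdname accessors
setMethod("regionCounts", "HaplotypeSet", function(x, ...) x@regionCounts)

#' Number of haplotypes
#' @param x A [HaplotypeSet-class].
#' @export
setMethod("length", "HaplotypeSet", function(x) length(x@hapIds))

setMethod("show", "HaplotypeSet", function(object) {
  cat(sprintf("HaplotypeSet [%s]: %d haplotype(s) from %d record(s)\n",
              object@marker, length(object@hapIds),
              sum(lengths(object@members))))
})

#' @rdname accessors
setMethod("limitJ", "ConnectionLimit", function(x, ...) x@limitJ)

setMethod("show", "ConnectionLimit", function(object) {
  cat(sprintf("ConnectionLimit: J = %d steps (L = %d characters, alpha = %g)\n",
              object@limitJ, object@L, object@alpha))
})

#' @rdname accessors
setMethod("networkEdges", "HaplotypeNetwork", function(x, ...) x@edges)

#' @describeIn accessors Named integer vector: connected-component index per
#'   haplotype.
setMethod("networkComponents", "HaplotypeNetwork", function(x, ...) {
  stats::setNames(x@component, x@haplotypes@hapIds)
})

#' @rdname accessors
setMethod("hapIds", "HaplotypeNetwork", function(x, ...) x@haplotypes@hapIds)

#' @rdname accessors
setMethod("regionCounts", "HaplotypeNetwork", function(x, ...) {
  x@haplotypes@regionCounts
})

#' @rdname accessors
setMethod("limitJ", "HaplotypeNetwork", function(x, ...) x@limit@limitJ)

setMethod("show", "HaplotypeNetwork", function(object) {
  cat(sprintf("HaplotypeNetwork: %d node(s), %d edge(s), %d component(s), limit J = %d\n",
              length(object@haplotypes@hapIds), nrow(object@edges),
              length(unique(object@component)), object@limit@limitJ))
})
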