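#' @import methods
NULL

## ---- controlled vocabularies ------------------------------------------------

#' Controlled vocabularies used throughout the package
#'
#' `markerLevels()` returns the marker names understood by the pipeline,
#' `syngenLevels()` the syngen labels of the *P. bursaria* species complex,
#' and `regionLevels()` the six-continent geographic vocabulary (plus
#' \code{"UNKNOWN"}).
#'
#' @return A character vector.
#' @export
#' @examples
#' syngenLevels()
markerLevels <- function() c("SSU", "ITS", "COI_nt", "COI_aa", "concat")

#' @rdname markerLevels
#' @export
syngenLevels <- function() c("R1", "R2", "R3", "R4", "R5")

#' @rdname markerLevels
#' @export
regionLevels <- function() {
  c("Europe", "Asia", "North America", "South America", "Australia",
    "Africa", "UNKNOWN")
}

## nucleotide alphabet: IUPAC codes + gap; U is normalized to T on input
.NT_ALPHABET <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                  "B", "D", "H", "V", "N", "-")
## peptide alphabet: the 20 amino acids + ambiguity codes, stop and gap
.AA_ALPHABET <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                  "B", "Z", "J", "U", "O", "X", "*", "-")
.NT_UNAMBIGUOUS <- c("A", "C", "G", "T")

#' Is a marker peptide-valued?
#' @param marker Marker name.
#' @return Logical.
#' @keywords internal
.isPeptideMarker <- function(marker) identical(marker, "COI_aa")

.alphabetFor <- function(marker) {
  if (.isPeptideMarker(marker)) .AA_ALPHABET else .NT_ALPHABET
}

## ---- MarkerAlignment --------------------------------------------------------

#' MarkerAlignment: an aligned set of sequence records for one marker
#'
#' Holds equal-length, upper-case sequences over a declared alphabet
#' (nucleotide IUPAC codes plus \code{"-"}, or amino-acid letters plus
#' \code{"-"}, \code{"X"}, \code{"*"}).  Column indices are 1-based in every
#' user-facing report, matching the convention used for signature position
#' numbering.
#'
#' @slot marker Marker name (see [markerLevels()]).
#' @slot ids Character vector of unique, whitespace-free record ids.
#' @slot seqs Character vector of aligned sequences, parallel to `ids`.
#' @slot desc Free-text descriptions (FASTA header remainder), parallel to
#'   `ids`.
#'
#' @seealso [readAlignment()], [writeAlignment()]
#' @export
setClass("MarkerAlignment",
         slots = c(marker = "character",
                   ids    = "character",
                   seqs   = "character",
                   desc   = "character"))

setValidity("MarkerAlignment", function(object) {
  msg <- character()
  if (length(object@marker) != 1L || !nzchar(object@marker))
    msg <- c(msg, "'marker' must be a single non-empty string")
  n <- length(object@ids)
  if (length(object@seqs) != n || length(object@desc) != n)
    msg <- c(msg, "'ids', 'seqs' and 'desc' must have equal length")
  if (n == 0L)
    msg <- c(msg, "alignment must contain at least one record")
  if (anyDuplicated(object@ids))
    msg <- c(msg, sprintf("duplicate record id: '%s'",
                          object@ids[duplicated(object@ids)][1L]))
  if (any(grepl("\\s", object@ids)))
    msg <- c(msg, "record ids must not contain whitespace")
  if (n > 0L) {
    len <- nchar(object@seqs)
    if (any(len == 0L))
      msg <- c(msg, sprintf("record '%s' has an empty sequence",
                            object@ids[len == 0L][1L]))
    if (length(unique(len)) > 1L) {
      bad <- object@ids[len != len[1L]][1L]
      msg <- c(msg, sprintf("ragged alignment: record '%s' has length %d, expected %d",
                            bad, nchar(object@seqs[object@ids == bad]), len[1L]))
    }
    alpha <- .alphabetFor(object@marker)
    for (i in seq_len(n)) {
      ch <- strsplit(object@seqs[i], "")[[1]]
      bad <- which(!(ch %in% alpha))
      if (length(bad)) {
        msg <- c(msg, sprintf("illegal character '%s' in record '%s' at column %d",
                              ch[bad[1L]], object@ids[i], bad[1L]))
        break
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a MarkerAlignment from ids and sequences
#'
#' Sequences are upper-cased and, for nucleotide markers, \code{U} is
#' normalized to \code{T}.
#'
#' @param ids Character vector of record ids.
#' @param seqs Character vector of aligned sequences.
#' @param marker Marker name, one of [markerLevels()].
#' @param desc Optional descriptions (defaults to empty strings).
#' @return A [MarkerAlignment-class] object.
#' @export
#' @examples
#' aln <- MarkerAlignment(c("a", "b"), c("ACGT", "ACGA"), "ITS")
#' alignmentLength(aln)
MarkerAlignment <- function(ids, seqs, marker, desc = NULL) {
  ids <- as.character(ids)
  seqs <- toupper(as.character(seqs))
  if (!.isPeptideMarker(marker))
    seqs <- gsub("U", "T", seqs, fixed = TRUE)
  if (is.null(desc)) desc <- character(length(ids))
  new("MarkerAlignment", marker = marker, ids = ids, seqs = seqs,
      desc = as.character(desc))
}

## ---- CladePartition ---------------------------------------------------------

#' CladePartition: record ids partitioned into syngen classes
#'
#' Maps every record id to a syngen label (\code{R1}..\code{R5}) or
#' \code{"UNKNOWN"}.  Labelled clades are the distinct non-UNKNOWN labels.
#'
#' @slot ids Character vector of record ids (unique).
#' @slot clade Character vector of labels, parallel to `ids`.
#' @export
setClass("CladePartition",
         slots = c(ids = "character", clade = "character"))

setValidity("CladePartition", function(object) {
  msg <- character()
  if (length(object@ids) != length(object@clade))
    msg <- c(msg, "'ids' and 'clade' must have equal length")
  if (anyDuplicated(object@ids))
    msg <- c(msg, "duplicate record id in partition")
  if (length(msg)) msg else TRUE
})

#' Construct a CladePartition
#' @param ids Record ids.
#' @param clade Syngen labels (or \code{"UNKNOWN"}), parallel to `ids`.
#' @return A [CladePartition-class] object.
#' @export
CladePartition <- function(ids, clade) {
  new("CladePartition", ids = as.character(ids), clade = as.character(clade))
}

## ---- ColumnProfileSet -------------------------------------------------------

#' ColumnProfileSet: per-column state multisets of variable alignment columns
#'
#' One entry per variable column: the observed (non-missing) character states
#' of each clade, and the number of records whose state at that column is
#' missing (gap, ambiguity code, or \code{X} in peptides) under the
#' \code{"ignore"} policy.
#'
#' @slot marker Marker name.
#' @slot columns Integer vector of 1-based variable column indices (sorted).
#' @slot states List parallel to `columns`; each element is a named list
#'   mapping clade label to the character vector of observed states (with
#'   multiplicity).
#' @slot nMissing Integer vector, parallel to `columns`.
#' @slot nRecords Number of records profiled.
#' @slot clades Clade labels present in the partition (UNKNOWN included when
#'   present).
#' @slot policy The missing-data policy used (\code{"ignore"} or
#'   \code{"as_state"}).
#' @seealso [findVariableColumns()]
#' @export
setClass("ColumnProfileSet",
         slots = c(marker = "character", columns = "integer",
                   states = "list", nMissing = "integer",
                   nRecords = "integer", clades = "character",
                   policy = "character"))

setValidity("ColumnProfileSet", function(object) {
  msg <- character()
  if (length(object@columns) != length(object@states) ||
      length(object@columns) != length(object@nMissing))
    msg <- c(msg, "'columns', 'states' and 'nMissing' must be parallel")
  if (is.unsorted(object@columns, strictly = TRUE) && length(object@columns) > 1L)
    msg <- c(msg, "'columns' must be strictly increasing")
  ## accounting: states + missing == records at every column
  for (k in seq_along(object@columns)) {
    tot <- sum(lengths(object@states[[k]])) + object@nMissing[k]
    if (tot != object@nRecords) {
      msg <- c(msg, sprintf("column %d: states (%d) + missing (%d) != records (%d)",
                            object@columns[k],
                            sum(lengths(object@states[[k]])),
                            object@nMissing[k], object@nRecords))
      break
    }
  }
  if (length(msg)) msg else TRUE
})

## ---- SignatureSet / CombinedSignature ---------------------------------------

.SIG_CATEGORIES <- c("SYNAPOMORPHY", "WITHIN_CLADE_VARIABLE", "OTHER_VARIABLE")

#' SignatureSet: classified variable columns of one marker
#'
#' The tabular analogue of a per-marker molecular signature: every variable
#' column with its category (fixed private synapomorphy, within-clade
#' variable, or other variable pattern), the clades it is diagnostic for, and
#' the collapsed per-clade state sets.
#'
#' @slot marker Marker name.
#' @slot clades Labelled clade set (fixed order, e.g. R1..R5).
#' @slot entries A data.frame with columns \code{column}, \code{category},
#'   \code{diagnostic_for} (comma-collapsed, empty unless SYNAPOMORPHY) and
#'   one \code{state_<clade>} column per clade (comma-collapsed observed
#'   state set, empty when all members are missing).
#' @seealso [classifyColumns()]
#' @export
setClass("SignatureSet",
         slots = c(marker = "character", clades = "character",
                   entries = "data.frame"))

setValidity("SignatureSet", function(object) {
  msg <- character()
  need <- c("column", "category", "diagnostic_for",
            paste0("state_", object@clades))
  miss <- setdiff(need, names(object@entries))
  if (length(miss))
    msg <- c(msg, paste("entries lack column(s):", paste(miss, collapse = ", ")))
  if (nrow(object@entries)) {
    if (!all(object@entries$category %in% .SIG_CATEGORIES))
      msg <- c(msg, "unknown category in entries")
    syn <- object@entries$category == "SYNAPOMORPHY"
    if (any(syn & !nzchar(object@entries$diagnostic_for)))
      msg <- c(msg, "SYNAPOMORPHY entries must name diagnostic clades")
    if (any(!syn & nzchar(object@entries$diagnostic_for)))
      msg <- c(msg, "non-SYNAPOMORPHY entries must have empty diagnostic_for")
  }
  if (length(msg)) msg else TRUE
})

#' CombinedSignature: signatures of several markers, merged
#'
#' Stacks per-marker signature tables and records, per clade, whether it is
#' separable (has at least one fixed private diagnostic state) by each marker
#' alone and by the combination of all markers.
#'
#' @slot clades Labelled clade set.
#' @slot entries As in [SignatureSet-class], with an extra leading
#'   \code{marker} column; ordered by (marker, column).
#' @slot separability A data.frame with one row per clade: logical columns
#'   per marker plus \code{combined}.
#' @seealso [combineMarkers()], [diagnosticTriples()]
#' @export
setClass("CombinedSignature",
         slots = c(clades = "character", entries = "data.frame",
                   separability = "data.frame"))

## ---- HaplotypeSet / HaplotypeNetwork ----------------------------------------

#' HaplotypeSet: records collapsed into haplotypes
#'
#' @slot marker Marker name.
#' @slot hapIds Haplotype ids (\code{"H1"}, \code{"H2"}, ... in order of first
#'   appearance).
#' @slot representative Representative sequence per haplotype (the member with
#'   fewest missing characters; ties broken by lexicographically smallest id).
#' @slot members List of member record-id vectors, parallel to `hapIds`.
#' @slot regionCounts Integer matrix (haplotypes x regions) aggregated from
#'   the sample metadata; rows sum to haplotype frequency.
#' @slot memberRegions Named character vector mapping every member record id
#'   to its region.
#' @seealso [collapseHaplotypes()]
#' @export
setClass("HaplotypeSet",
         slots = c(marker = "character", hapIds = "character",
                   representative = "character", members = "list",
                   regionCounts = "matrix", memberRegions = "character"))

setValidity("HaplotypeSet", function(object) {
  msg <- character()
  n <- length(object@hapIds)
  if (length(object@representative) != n || length(object@members) != n ||
      nrow(object@regionCounts) != n)
    msg <- c(msg, "haplotype slots must be parallel")
  if (any(lengths(object@members) == 0L))
    msg <- c(msg, "every haplotype must have at least one member")
  if (n > 0L &&
      !all(rowSums(object@regionCounts) == lengths(object@members)))
    msg <- c(msg, "regionCounts rows must sum to haplotype frequency")
  if (length(msg)) msg else TRUE
})

#' ConnectionLimit: the statistical-parsimony connection limit
#'
#' @slot L Number of compared characters.
#' @slot alpha Parsimony confidence level (default 0.95).
#' @slot limitJ Largest number of mutational steps connectable at `alpha`.
#' @slot probs Numeric vector of no-homoplasy probabilities P_j for
#'   j = 1..min(L, limitJ + 1) (at least the evaluated prefix).
#' @seealso [connectionLimit()]
#' @export
setClass("ConnectionLimit",
         slots = c(L = "integer", alpha = "numeric", limitJ = "integer",
                   probs = "numeric"))

setValidity("ConnectionLimit", function(object) {
  msg <- character()
  if (object@L < 1L) msg <- c(msg, "L must be >= 1")
  if (object@alpha <= 0 || object@alpha >= 1)
    msg <- c(msg, "alpha must be in (0, 1)")
  if (object@limitJ < 0L) msg <- c(msg, "limitJ must be >= 0")
  if (length(msg)) msg else TRUE
})

#' HaplotypeNetwork: a statistical-parsimony haplotype network
#'
#' Nodes are haplotypes; edges connect haplotypes whose representatives are
#' at most `limitJ` mutational steps apart, added in non-decreasing step
#' order (ties between previously disconnected components are all retained,
#' producing reticulations).
#'
#' @slot haplotypes The [HaplotypeSet-class] the network was built from.
#' @slot edges A data.frame with columns \code{from}, \code{to} (haplotype
#'   ids) and \code{steps}.
#' @slot component Integer vector: connected-component index per haplotype.
#' @slot limit The [ConnectionLimit-class] used.
#' @seealso [buildNetwork()]
#' @export
setClass("HaplotypeNetwork",
         slots = c(haplotypes = "HaplotypeSet", edges = "data.frame",
                   component = "integer", limit = "ConnectionLimit"))

setValidity("HaplotypeNetwork", function(object) {
  msg <- character()
  if (nrow(object@edges) &&
      any(object@edges$steps > object@limit@limitJ))
    msg <- c(msg, "edge exceeds the connection limit")
  if (length(object@component) != length(object@haplotypes@hapIds))
    msg <- c(msg, "'component' must be parallel to haplotypes")
  if (length(msg)) msg else TRUE
})
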