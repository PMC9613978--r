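## Reading and writing aligned sequence data and sample metadata.

#' Read an aligned marker file (FASTA or NEXUS)
#'
#' Reads a pre-aligned sequence file into a [MarkerAlignment-class].  All
#' records must have equal length; sequences are upper-cased and, for
#' nucleotide markers, \code{U} is normalized to \code{T}.  The FASTA id is
#' the header up to the first whitespace; the remainder is kept as a
#' free-text description.  NEXUS support covers the DATA/CHARACTERS block
#' with a simple MATRIX (sequential or interleaved); other commands are
#' ignored.
#'
#' @param path Path to the file.
#' @param marker Marker name, one of [markerLevels()].
#' @param format \code{"auto"} (by extension), \code{"fasta"} or
#'   \code{"nexus"}.
#' @return A [MarkerAlignment-class]; record order follows the file.
#' @export
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "ACGT", ">b", "ACGA"), f)
#' readAlignment(f, "ITS")
readAlignment <- function(path, marker = c("SSU", "ITS", "COI_nt", "COI_aa"),
                          format = c("auto", "fasta", "nexus")) {
  marker <- match.arg(marker)
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(nex|nexus|nxs)$", path, ignore.case = TRUE))
      "nexus" else "fasta"
  }
  if (format == "fasta") {
    if (file.size(path) == 0L) stop("empty alignment file: ", path)
    set <- Biostrings::readBStringSet(path)
    if (length(set) == 0L) stop("empty alignment file: ", path)
    hdr <- names(set)
    ids <- sub("\\s.*$", "", hdr)
    desc <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), "")
    seqs <- as.character(set)
  } else {
    lst <- ape::read.nexus.data(path)
    if (length(lst) == 0L) stop("empty alignment file: ", path)
    ids <- names(lst)
    desc <- character(length(lst))
    seqs <- vapply(lst, function(x) paste(x, collapse = ""), character(1))
  }
  len <- nchar(seqs)
  if (length(unique(len)) > 1L) {
    bad <- ids[len != len[1L]][1L]
    stop(sprintf("ragged alignment: record '%s' has length %d, expected %d",
                 bad, len[ids == bad][1L], len[1L]))
  }
  MarkerAlignment(ids, seqs, marker, desc)
}

#' Write an alignment to FASTA or NEXUS
#'
#' @param aln A [MarkerAlignment-class].
#' @param path Output path.
#' @param format \code{"fasta"} or \code{"nexus"}.
#' @return Invisibly, `path`.
#' @export
writeAlignment <- function(aln, path, format = c("fasta", "nexus")) {
  format <- match.arg(format)
  stopifnot(is(aln, "MarkerAlignment"))
  if (format == "fasta") {
    nm <- ifelse(nzchar(aln@desc), paste(aln@ids, aln@desc), aln@ids)
    set <- Biostrings::BStringSet(stats::setNames(aln@seqs, nm))
    Biostrings::writeXStringSet(set, path, width = 70L)
  } else {
    ape::write.nexus.data(strsplit(stats::setNames(aln@seqs, aln@ids), ""),
                          file = path, interleaved = FALSE,
                          format = if (.isPeptideMarker(aln@marker))
                            "protein" else "dna")
  }
  invisible(path)
}

#' Read a sample metadata table
#'
#' Reads a TSV with header and required columns \code{id}, \code{syngen} and
#' \code{region}; optional columns \code{strain} and \code{endosymbiont} are
#' carried through.  Blank or "unknown" syngen/region values map to
#' \code{"UNKNOWN"}.  Region values must belong to the six-continent
#' vocabulary of [regionLevels()] (case-insensitive; underscores accepted
#' for spaces).
#'
#' @param path Path to the TSV file.
#' @return A data.frame with columns \code{id}, \code{syngen},
#'   \code{region}, \code{strain}, \code{endosymbiont}.
#' @export
readMetadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE,
                          quote = "", comment.char = "")
  need <- c("id", "syngen", "region")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("metadata lacks required column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$id))
    stop("duplicate id in metadata: '", df$id[duplicated(df$id)][1L], "'")
  norm <- function(x, levels) {
    x <- trimws(x)
    x[is.na(x) | !nzchar(x) | tolower(x) == "unknown"] <- "UNKNOWN"
    key <- tolower(gsub("_", " ", x))
    hit <- match(key, tolower(levels))
    if (anyNA(hit))
      stop("unrecognized value in metadata: '", x[is.na(hit)][1L], "'")
    levels[hit]
  }
  df$syngen <- norm(df$syngen, c(syngenLevels(), "UNKNOWN"))
  df$region <- norm(df$region, regionLevels())
  if (is.null(df$strain)) df$strain <- ""
  if (is.null(df$endosymbiont)) df$endosymbiont <- ""
  df[, c("id", "syngen", "region", "strain", "endosymbiont")]
}

#' Write a sample metadata table
#'
#' @param meta A metadata data.frame as returned by [readMetadata()].
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
writeMetadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Join an alignment with sample metadata into a clade partition
#'
#' @param aln A [MarkerAlignment-class].
#' @param meta A metadata data.frame (columns \code{id}, \code{syngen}).
#' @param requireAll If TRUE, every alignment record must appear in the
#'   metadata (error otherwise); if FALSE, missing records become
#'   \code{"UNKNOWN"}.
#' @return A [CladePartition-class] over the alignment's record ids.
#' @export
joinAlignmentMetadata <- function(aln, meta, requireAll = FALSE) {
  stopifnot(is(aln, "MarkerAlignment"))
  hit <- match(aln@ids, meta$id)
  if (requireAll && anyNA(hit))
    stop("record(s) missing from metadata: ",
         paste(utils::head(aln@ids[is.na(hit)], 5L), collapse = ", "))
  clade <- ifelse(is.na(hit), "UNKNOWN", meta$syngen[hit])
  CladePartition(aln@ids, clade)
}

#' Drop columns that are gap-only across all records
#'
#' Utility for alignments arising from record subsetting; it is never
#' applied implicitly by any other operation.
#'
#' @param aln A [MarkerAlignment-class].
#' @return A [MarkerAlignment-class] without all-gap columns; the 1-based
#'   indices of the kept columns (relative to the input) are attached as
#'   attribute \code{"kept_columns"}.
#' @export
dropGapOnlyColumns <- function(aln) {
  m <- seqMatrix(aln)
  keep <- which(colSums(m != "-") > 0L)
  out <- aln[, j = keep]
  attr(out, "kept_columns") <- keep
  out
}
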