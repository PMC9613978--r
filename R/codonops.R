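## Genetic-code handling and translation of COI nucleotide alignments.

#' Fetch a genetic code by NCBI translation-table number
#'
#' Supported tables: 1 (standard), 4 (mold/protozoan/coelenterate
#' mitochondrial, in which TGA encodes Trp), and 6 (ciliate nuclear, in
#' which TAA/TAG encode Gln).  COI is a mitochondrial gene, so table 4 is
#' the package default wherever a code is needed.
#'
#' @param tableId Integer: 1, 4 or 6.
#' @return A list with elements \code{table_id}, \code{codons} (named
#'   character: 64 codons to amino-acid letters, stops as \code{"*"}) and
#'   \code{start_codons}.
#' @export
#' @examples
#' geneticCode(4)$codons[["TGA"]]   # "W"
geneticCode <- function(tableId = 4) {
  tableId <- as.integer(tableId)
  if (!tableId %in% c(1L, 4L, 6L))
    stop("unsupported translation table: ", tableId,
         " (supported: 1, 4, 6)")
  gc <- Biostrings::getGeneticCode(as.character(tableId))
  ## alt_init_codons attribute lists alternative starts; ATG is always one
  starts <- unique(c("ATG", attr(gc, "alt_init_codons")))
  if (length(gc) != 64L) stop("internal: genetic code must have 64 codons")
  list(table_id = tableId, codons = gc, start_codons = starts)
}

.splitCodons <- function(seq, frame) {
  n <- nchar(seq)
  usable <- n - frame + 1L
  k <- usable %/% 3L
  if (k < 1L) return(character(0))
  starts <- frame + 3L * (seq_len(k) - 1L)
  substring(seq, starts, starts + 2L)
}

.translateCodons <- function(codons, code) {
  ## codons with any gap or ambiguity character translate to X
  aa <- unname(code$codons[codons])
  aa[is.na(aa)] <- "X"
  aa
}

#' Translate a COI nucleotide alignment to amino acids
#'
#' Translates codon-by-codon in the given frame under the chosen genetic
#' code.  Codons containing a gap or ambiguity character translate to
#' \code{X}; a trailing incomplete codon is dropped.  The returned codon
#' column map links every amino-acid column to its three source nucleotide
#' columns, so amino-acid synapomorphies can be traced back to the
#' nucleotide alignment.
#'
#' @param aln A nucleotide [MarkerAlignment-class] (marker \code{"COI_nt"}).
#' @param code A genetic code from [geneticCode()] (default table 4).
#' @param frame Reading frame: 1, 2 or 3.
#' @return A list with elements \code{aa} (a [MarkerAlignment-class] with
#'   marker \code{"COI_aa"}) and \code{map} (data.frame \code{aa_column},
#'   \code{nt1}, \code{nt2}, \code{nt3}; all 1-based).
#' @export
#' @examples
#' aln <- MarkerAlignment("x", "ATGTGA", "COI_nt")
#' translateAlignment(aln, geneticCode(4))$aa
translateAlignment <- function(aln, code = geneticCode(4), frame = 1L) {
  stopifnot(is(aln, "MarkerAlignment"))
  frame <- as.integer(frame)
  if (!frame %in% 1:3) stop("frame must be 1, 2 or 3")
  len <- alignmentLength(aln)
  k <- (len - frame + 1L) %/% 3L
  if (k < 1L)
    stop(sprintf("alignment of length %d has no complete codon in frame %d",
                 len, frame))
  aaSeqs <- vapply(aln@seqs, function(s) {
    paste(.translateCodons(.splitCodons(s, frame), code), collapse = "")
  }, character(1), USE.NAMES = FALSE)
  aa <- new("MarkerAlignment", marker = "COI_aa", ids = aln@ids,
            seqs = aaSeqs, desc = aln@desc)
  nt1 <- frame + 3L * (seq_len(k) - 1L)
  map <- data.frame(aa_column = seq_len(k), nt1 = nt1, nt2 = nt1 + 1L,
                    nt3 = nt1 + 2L)
  list(aa = aa, map = map)
}

#' Pick the reading frame with fewest internal stop codons
#'
#' Translates the alignment in all three frames and returns the frame
#' minimizing the total number of internal stop codons across records
#' (stops in the final codon of a record are not counted).  Ties are broken
#' toward the lower frame number.
#'
#' @param aln A nucleotide [MarkerAlignment-class].
#' @param code A genetic code from [geneticCode()].
#' @return The chosen frame (integer 1..3), with the per-frame internal
#'   stop counts attached as attribute \code{"stops"}.
#' @export
pickFrame <- function(aln, code = geneticCode(4)) {
  stopifnot(is(aln, "MarkerAlignment"))
  stops <- vapply(1:3, function(fr) {
    k <- (alignmentLength(aln) - fr + 1L) %/% 3L
    if (k < 1L) return(Inf)
    sum(vapply(aln@seqs, function(s) {
      aa <- .translateCodons(.splitCodons(s, fr), code)
      sum(aa[-length(aa)] == "*")
    }, numeric(1)))
  }, numeric(1))
  best <- which.min(stops)   # ties resolve to the lowest frame
  message(sprintf("pickFrame: internal stops by frame: %s; chose frame %d",
                  paste(sprintf("%d=%s", 1:3, format(stops)), collapse = ", "),
                  best))
  structure(as.integer(best), stops = stops)
}
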