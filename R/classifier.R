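## Signature-based assignment of query sequences to syngens, including the
## mapping of unaligned (possibly partial) queries onto reference alignment
## columns.

#' Majority-state consensus of a reference alignment
#'
#' The consensus takes the most frequent character per column, gaps and
#' missing characters excluded; columns where the gap is the majority
#' character are dropped.  Ties go to the alphabetically first state.
#'
#' @param aln A [MarkerAlignment-class].
#' @return A single consensus string with the 1-based reference columns it
#'   retains attached as attribute \code{"columns"}.
#' @export
consensusSequence <- function(aln) {
  m <- seqMatrix(aln)
  keep <- integer(); cons <- character()
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    if (sum(col == "-") * 2L > length(col)) next  # gap-majority column
    obs <- col[!.isMissingState(col, aln@marker)]
    if (!length(obs)) next
    tab <- sort(table(obs), decreasing = TRUE)
    top <- names(tab)[tab == tab[1L]]
    keep <- c(keep, j)
    cons <- c(cons, sort(top)[1L])
  }
  structure(paste(cons, collapse = ""), columns = keep)
}

#' Map an unaligned query onto reference alignment columns
#'
#' Globally aligns the (gap-stripped) query against the majority consensus
#' of the reference alignment with free end gaps (match +1, mismatch -1,
#' gap -2), so partial sequences map onto the leading or trailing columns
#' they actually cover.  The result is a strictly monotone mapping from
#' 1-based ungapped query positions to 1-based reference alignment columns.
#'
#' @param query A single sequence string (gaps are stripped) or a named
#'   length-1 character vector.
#' @param refAln The reference [MarkerAlignment-class].
#' @return A data.frame with columns \code{query_pos} and \code{ref_column};
#'   the aligned identity fraction (matches over aligned non-gap pairs) is
#'   attached as attribute \code{"identity"}.
#' @export
mapQueryToReference <- function(query, refAln) {
  stopifnot(is(refAln, "MarkerAlignment"))
  q <- toupper(gsub("-", "", query[[1]], fixed = TRUE))
  if (!.isPeptideMarker(refAln@marker)) q <- gsub("U", "T", q, fixed = TRUE)
  if (!nzchar(q)) stop("empty query")
  cons <- consensusSequence(refAln)
  refCols <- attr(cons, "columns")

  alpha <- .alphabetFor(refAln@marker)
  sub <- matrix(-1, length(alpha), length(alpha),
                dimnames = list(alpha, alpha))
  diag(sub) <- 1
  pa <- Biostrings::pairwiseAlignment(
    pattern = q, subject = as.character(cons), type = "overlap",
    substitutionMatrix = sub, gapOpening = 0, gapExtension = 2)
  pat <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  sbj <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  qpos <- Biostrings::start(Biostrings::pattern(pa)) - 1L
  spos <- Biostrings::start(Biostrings::subject(pa)) - 1L
  qs <- integer(); rs <- integer(); match <- 0L; pairs <- 0L
  for (k in seq_along(pat)) {
    pgap <- pat[k] == "-"; sgap <- sbj[k] == "-"
    if (!pgap) qpos <- qpos + 1L
    if (!sgap) spos <- spos + 1L
    if (!pgap && !sgap) {
      qs <- c(qs, qpos); rs <- c(rs, refCols[spos])
      pairs <- pairs + 1L
      if (pat[k] == sbj[k]) match <- match + 1L
    }
  }
  out <- data.frame(query_pos = qs, ref_column = rs)
  attr(out, "identity") <- if (pairs) match / pairs else 0
  out
}

.finalCallString <- function(call, clades) {
  switch(call,
         ASSIGNED = paste0("ASSIGNED(", clades, ")"),
         AMBIGUOUS = paste0("AMBIGUOUS(", paste(clades, collapse = ","), ")"),
         call)
}

#' Type a query sequence against a combined signature
#'
#' For every clade, the query is checked at each diagnostic (marker,
#' column, state) triple whose column it covers with a non-missing state
#' ("evaluable").  A clade matches when it has >= 1 evaluable triple and the
#' query state equals the clade state at every one of them; a clade with an
#' evaluable mismatch is excluded; a clade with no evaluable triple is
#' neither matched nor excluded.  The final call is
#' \code{ASSIGNED(<clade>)} when exactly one clade matches,
#' \code{AMBIGUOUS(<set>)} when several matched clades tie -- or, with no
#' positive match, when >= 2 unexcluded clades remain (the SSU-only R1/R2
#' situation), \code{INSUFFICIENT} when fewer than `minEvaluable` distinct
#' diagnostic columns were covered, and \code{CONFLICT} otherwise.
#'
#' @param query A named length-1 character vector (name = query id) or a
#'   plain string.
#' @param sig A [CombinedSignature-class].
#' @param refAlns Named list of reference [MarkerAlignment-class] objects
#'   (names are marker names).
#' @param marker Marker of the query (must be present in `sig` and
#'   `refAlns`).
#' @param minEvaluable Minimum number of distinct covered diagnostic
#'   columns for a confident call (default 3).
#' @return A list with elements \code{query_id}, \code{marker},
#'   \code{matched} (character vector), \code{excluded},
#'   \code{n_evaluable}, \code{conflicts} (data.frame \code{clade},
#'   \code{column}, \code{expected}, \code{observed}), \code{final_call}
#'   (string) and \code{call_type} (one of ASSIGNED, AMBIGUOUS, CONFLICT,
#'   INSUFFICIENT).
#' @export
typeQuery <- function(query, sig, refAlns, marker, minEvaluable = 3L) {
  stopifnot(is(sig, "CombinedSignature"))
  qid <- if (!is.null(names(query))) names(query)[1L] else "query"
  triples <- diagnosticTriples(sig)
  triples <- triples[triples$marker == marker, , drop = FALSE]
  if (!marker %in% unique(sig@entries$marker))
    stop("marker '", marker, "' absent from signature")
  if (is.null(refAlns[[marker]]))
    stop("no reference alignment for marker '", marker, "'")

  mapping <- mapQueryToReference(query, refAlns[[marker]])
  qchars <- strsplit(toupper(gsub("-", "", query[[1]], fixed = TRUE)), "")[[1]]
  if (!.isPeptideMarker(marker)) qchars <- gsub("U", "T", qchars, fixed = TRUE)

  obsAt <- function(col) {
    k <- match(col, mapping$ref_column)
    if (is.na(k)) return(NA_character_)
    ch <- qchars[mapping$query_pos[k]]
    if (.isMissingState(ch, marker)) NA_character_ else ch
  }
  triples$observed <- vapply(triples$column, obsAt, character(1))
  eval <- !is.na(triples$observed)
  nEvaluable <- length(unique(triples$column[eval]))

  clades <- sig@clades
  matched <- character(); excluded <- character(); unknown <- character()
  conflicts <- list()
  for (cc in clades) {
    tc <- triples[triples$clade == cc & eval, , drop = FALSE]
    if (nrow(tc) == 0L) { unknown <- c(unknown, cc); next }
    bad <- tc$observed != tc$state
    if (any(bad)) {
      excluded <- c(excluded, cc)
      conflicts[[cc]] <- data.frame(clade = cc, column = tc$column[bad],
                                    expected = tc$state[bad],
                                    observed = tc$observed[bad])
    } else matched <- c(matched, cc)
  }
  conflicts <- if (length(conflicts)) do.call(rbind, conflicts) else
    data.frame(clade = character(), column = integer(),
               expected = character(), observed = character())
  rownames(conflicts) <- NULL

  if (nEvaluable < minEvaluable) {
    type <- "INSUFFICIENT"; callSet <- character()
  } else if (length(matched) == 1L) {
    type <- "ASSIGNED"; callSet <- matched
  } else if (length(matched) >= 2L) {
    type <- "AMBIGUOUS"; callSet <- matched
  } else if (length(unknown) >= 2L) {
    type <- "AMBIGUOUS"; callSet <- unknown
  } else {
    type <- "CONFLICT"; callSet <- character()
  }
  list(query_id = qid, marker = marker, matched = matched,
       excluded = excluded, unknown = unknown, n_evaluable = nEvaluable,
       conflicts = conflicts, call_type = type, call_set = callSet,
       final_call = .finalCallString(type, callSet))
}

#' Type a batch of queries
#'
#' Applies [typeQuery()] to every record; per-record errors are captured,
#' never aborting the batch.  When metadata is supplied, region information
#' is joined for the biogeography stage.
#'
#' @param queries Named character vector of query sequences.
#' @param sig A [CombinedSignature-class].
#' @param refAlns Named list of reference alignments.
#' @param marker Marker of the queries.
#' @param minEvaluable See [typeQuery()].
#' @param meta Optional metadata data.frame (columns \code{id},
#'   \code{region}).
#' @return A data.frame with one row per query: \code{query_id},
#'   \code{marker}, \code{call_type}, \code{final_call}, \code{n_evaluable},
#'   \code{region} and \code{error} (empty unless the record failed).
#' @export
batchType <- function(queries, sig, refAlns, marker, minEvaluable = 3L,
                      meta = NULL) {
  ids <- names(queries)
  if (is.null(ids)) ids <- paste0("query", seq_along(queries))
  rows <- lapply(seq_along(queries), function(i) {
    res <- tryCatch(
      typeQuery(stats::setNames(queries[i], ids[i]), sig, refAlns, marker,
                minEvaluable),
      error = function(e) e)
    if (inherits(res, "error")) {
      data.frame(query_id = ids[i], marker = marker, call_type = "ERROR",
                 final_call = "", n_evaluable = NA_integer_,
                 error = conditionMessage(res))
    } else {
      data.frame(query_id = ids[i], marker = marker,
                 call_type = res$call_type, final_call = res$final_call,
                 n_evaluable = res$n_evaluable, error = "")
    }
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(query_id = character(), marker = character(),
                      call_type = character(), final_call = character(),
                      n_evaluable = integer(), error = character())
  out$region <- rep("UNKNOWN", nrow(out))
  if (!is.null(meta) && nrow(out)) {
    hit <- match(out$query_id, meta$id)
    out$region[!is.na(hit)] <- meta$region[hit[!is.na(hit)]]
  }
  out
}
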