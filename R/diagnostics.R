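## Synapomorphy discovery: variable-column detection and classification into
## fixed private diagnostic characters vs. within-clade variable sites.

#' Missing-state predicate
#'
#' Under the default policy, gaps and ambiguity codes (and \code{X} in
#' peptides) are treated as missing data: they never match anything and are
#' excluded from state sets.  For nucleotides the observable states are
#' A/C/G/T; for peptides the 20 amino acids plus \code{*}.
#'
#' @param chars Character vector of single characters.
#' @param marker Marker name.
#' @return Logical vector: TRUE where the character is missing.
#' @keywords internal
.isMissingState <- function(chars, marker) {
  if (.isPeptideMarker(marker)) {
    !(chars %in% setdiff(.AA_ALPHABET, c("B", "Z", "J", "U", "O", "X", "-")))
  } else {
    !(chars %in% .NT_UNAMBIGUOUS)
  }
}

#' Find variable alignment columns
#'
#' Profiles every column with at least two distinct states.  Under
#' \code{missingPolicy = "ignore"} (default) gaps/ambiguity codes are
#' excluded, so a column is variable when it shows >= 2 distinct
#' non-missing states; under \code{"as_state"} gap and ambiguity characters
#' count as states of their own.
#'
#' @param aln A [MarkerAlignment-class].
#' @param partition A [CladePartition-class] covering the alignment ids.
#' @param missingPolicy \code{"ignore"} or \code{"as_state"}.
#' @return A [ColumnProfileSet-class], sorted by column.
#' @export
findVariableColumns <- function(aln, partition,
                                missingPolicy = c("ignore", "as_state")) {
  missingPolicy <- match.arg(missingPolicy)
  stopifnot(is(aln, "MarkerAlignment"), is(partition, "CladePartition"))
  if (length(aln) < 2L) stop("need at least 2 records")
  cl <- cladeOf(partition)[aln@ids]
  if (anyNA(cl)) stop("partition does not cover all alignment records")
  m <- seqMatrix(aln)
  cladeSet <- unique(cl)
  known <- intersect(c(syngenLevels(), "UNKNOWN"), cladeSet)
  cladeSet <- c(known, sort(setdiff(cladeSet, known)))

  columns <- integer(); states <- list(); nMiss <- integer()
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    miss <- .isMissingState(col, aln@marker)
    distinct <- if (missingPolicy == "ignore") unique(col[!miss]) else unique(col)
    if (length(distinct) < 2L) next
    columns <- c(columns, j)
    nMiss <- c(nMiss, sum(miss))
    byClade <- lapply(cladeSet, function(cc) unname(col[cl == cc & !miss]))
    names(byClade) <- cladeSet
    states[[length(states) + 1L]] <- byClade
  }
  new("ColumnProfileSet", marker = aln@marker, columns = columns,
      states = states, nMissing = nMiss, nRecords = length(aln),
      clades = cladeSet, policy = missingPolicy)
}

## fixed state of a clade at a column: the single non-missing state shared by
## all its members, or NA when the clade is internally variable or all-missing
.fixedState <- function(obs) {
  u <- unique(obs)
  if (length(u) == 1L) u else NA_character_
}

#' Classify variable columns into signature categories
#'
#' Every profiled column becomes exactly one signature entry:
#' \describe{
#'   \item{SYNAPOMORPHY}{some labelled clade is fixed for a state carried by
#'     no record outside that clade; `diagnostic_for` lists all such clades.}
#'   \item{WITHIN_CLADE_VARIABLE}{no clade is diagnostic and at least one
#'     labelled clade shows >= 2 non-missing states.}
#'   \item{OTHER_VARIABLE}{anything else, e.g. a fixed difference shared by
#'     two clades (the R1+R2 pattern in the SSU).}
#' }
#' A clade counts as fixed when all its non-missing members agree and at
#' least one member is non-missing.  Records labelled \code{"UNKNOWN"} never
#' found a synapomorphy themselves but do participate in the exclusivity
#' check.
#'
#' @param profiles A [ColumnProfileSet-class] from [findVariableColumns()].
#' @param partition The [CladePartition-class] used to build the profiles.
#' @param minCladeSize Clades smaller than this trigger a warning message
#'   (they still produce synapomorphies; single-member clades are legitimate
#'   here: syngen R5 is represented by a single strain).
#' @return A [SignatureSet-class].
#' @export
classifyColumns <- function(profiles, partition, minCladeSize = 1L) {
  stopifnot(is(profiles, "ColumnProfileSet"), is(partition, "CladePartition"))
  labelled <- setdiff(profiles@clades, "UNKNOWN")
  if (length(labelled) < 2L || length(cladeLevels(partition)) < 2L)
    stop("need at least 2 labelled clades to classify columns")
  sizes <- table(factor(cladeOf(partition), levels = labelled))
  small <- names(sizes)[sizes < minCladeSize]
  if (length(small))
    message("classifyColumns: clade(s) below minCladeSize (weakly supported): ",
            paste(small, collapse = ", "))

  n <- length(profiles@columns)
  category <- character(n); diagFor <- character(n)
  stateCols <- matrix("", nrow = n, ncol = length(labelled),
                      dimnames = list(NULL, labelled))
  for (k in seq_len(n)) {
    byClade <- profiles@states[[k]]
    obsLab <- byClade[labelled]
    fixed <- vapply(obsLab, .fixedState, character(1))
    diag <- character()
    for (cc in labelled) {
      s <- fixed[[cc]]
      if (is.na(s)) next
      outside <- unlist(byClade[setdiff(names(byClade), cc)], use.names = FALSE)
      if (!(s %in% outside)) diag <- c(diag, cc)
    }
    withinVar <- any(vapply(obsLab, function(o) length(unique(o)) >= 2L,
                            logical(1)))
    category[k] <- if (length(diag)) "SYNAPOMORPHY"
                   else if (withinVar) "WITHIN_CLADE_VARIABLE"
                   else "OTHER_VARIABLE"
    diagFor[k] <- paste(diag, collapse = ",")
    stateCols[k, ] <- vapply(obsLab, function(o)
      paste(sort(unique(o)), collapse = ","), character(1))
  }
  entries <- data.frame(column = profiles@columns, category = category,
                        diagnostic_for = diagFor, stringsAsFactors = FALSE)
  for (cc in labelled) entries[[paste0("state_", cc)]] <- stateCols[, cc]
  new("SignatureSet", marker = profiles@marker, clades = labelled,
      entries = entries)
}

#' Combine per-marker signatures and assess clade separability
#'
#' Stacks the diagnostic information of several markers and reports, per
#' clade, whether it is separable from every other clade using each marker
#' alone and using the combination.  A clade is separable by a marker when
#' it carries at least one fixed private diagnostic state (a SYNAPOMORPHY
#' entry diagnostic for it) in that marker; such a state distinguishes the
#' clade from all others by construction.
#'
#' @param tables A list of [SignatureSet-class] objects (>= 1) over the same
#'   clade set.
#' @return A [CombinedSignature-class].
#' @export
combineMarkers <- function(tables) {
  if (is(tables, "SignatureSet")) tables <- list(tables)
  stopifnot(length(tables) >= 1L,
            all(vapply(tables, is, logical(1), "SignatureSet")))
  clades <- tables[[1]]@clades
  for (t in tables[-1])
    if (!identical(sort(t@clades), sort(clades)))
      stop("clade sets differ across signature tables")
  entries <- do.call(rbind, lapply(tables, function(t) {
    e <- t@entries
    if (nrow(e) == 0L) {
      e <- e[, c("column", "category", "diagnostic_for",
                 paste0("state_", clades)), drop = FALSE]
      return(cbind(data.frame(marker = character()), e))
    }
    cbind(data.frame(marker = t@marker, stringsAsFactors = FALSE),
          e[, c("column", "category", "diagnostic_for",
                paste0("state_", clades))])
  }))
  entries <- entries[order(match(entries$marker, markerLevels()),
                           entries$column), , drop = FALSE]
  rownames(entries) <- NULL

  markers <- vapply(tables, function(t) t@marker, character(1))
  sep <- data.frame(clade = clades, stringsAsFactors = FALSE)
  for (t in tables) {
    dg <- diagnosticTriples(t)
    sep[[t@marker]] <- clades %in% dg$clade
  }
  sep$combined <- apply(as.matrix(sep[, markers, drop = FALSE]), 1L, any)
  new("CombinedSignature", clades = clades, entries = entries,
      separability = sep)
}

#' Write a signature report as TSV
#'
#' One row per (marker, column) in stable (marker, column) order, with the
#' per-clade state columns in fixed clade order, the category and the
#' clades the column is diagnostic for.  The file round-trips through
#' [readSignatureReport()].
#'
#' @param sig A [CombinedSignature-class] (or a single [SignatureSet-class],
#'   which is combined first).
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
writeSignatureReport <- function(sig, path) {
  if (is(sig, "SignatureSet")) sig <- combineMarkers(list(sig))
  stopifnot(is(sig, "CombinedSignature"))
  utils::write.table(sig@entries, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a signature report written by [writeSignatureReport()]
#'
#' @param path TSV path.
#' @return A [CombinedSignature-class]; separability is recomputed from the
#'   entries.
#' @export
readSignatureReport <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  stateCols <- grep("^state_", names(df), value = TRUE)
  clades <- sub("^state_", "", stateCols)
  df$column <- as.integer(df$column)
  tables <- lapply(unique(df$marker), function(mk) {
    e <- df[df$marker == mk,
            c("column", "category", "diagnostic_for", stateCols),
            drop = FALSE]
    rownames(e) <- NULL
    new("SignatureSet", marker = mk, clades = clades, entries = e)
  })
  if (!length(tables))
    return(new("CombinedSignature", clades = clades,
               entries = df[, c("marker", "column", "category",
                                "diagnostic_for", stateCols), drop = FALSE],
               separability = data.frame(clade = clades, combined = FALSE)))
  combineMarkers(tables)
}
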