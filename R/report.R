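## End-to-end pipeline: discovery -> typing -> networks -> tree check, with
## a single summary artifact. This is also what the command-line front end
## (inst/scripts/syngenmark.R) drives.

#' Discover the combined molecular signature of a dataset
#'
#' Runs variable-column detection and classification on each supplied
#' marker (translating COI to amino acids first) and combines the
#' per-marker signature tables.
#'
#' @param alignments Named list of [MarkerAlignment-class] objects; names
#'   among \code{SSU}, \code{ITS}, \code{COI_nt}, \code{COI_aa}.
#' @param meta Metadata data.frame (columns \code{id}, \code{syngen}).
#' @param translTable Genetic code for COI translation (default 4,
#'   mold/protozoan mitochondrial).
#' @param frame COI reading frame (default 1); use [pickFrame()] to choose
#'   one from the data.
#' @param missingPolicy Passed to [findVariableColumns()].
#' @param minCladeSize Passed to [classifyColumns()].
#' @return A list with \code{signature} (a [CombinedSignature-class]),
#'   \code{tables} (per-marker [SignatureSet-class] list), \code{profiles}
#'   (per-marker [ColumnProfileSet-class] list), \code{coiMap} (codon
#'   column map or NULL) and \code{refAlns} (reference alignments keyed by
#'   signature marker, COI at the amino-acid level).
#' @export
discoverSignatures <- function(alignments, meta, translTable = 4,
                               frame = 1L, missingPolicy = "ignore",
                               minCladeSize = 1L) {
  tables <- list(); profiles <- list(); refAlns <- list(); coiMap <- NULL
  for (mk in names(alignments)) {
    aln <- alignments[[mk]]
    if (mk == "COI_nt") {
      tr <- translateAlignment(aln, geneticCode(translTable), frame)
      aln <- tr$aa; coiMap <- tr$map; mk <- "COI_aa"
    }
    part <- joinAlignmentMetadata(aln, meta)
    prof <- findVariableColumns(aln, part, missingPolicy)
    tables[[mk]] <- classifyColumns(prof, part, minCladeSize)
    profiles[[mk]] <- prof
    refAlns[[mk]] <- aln
  }
  list(signature = combineMarkers(unname(tables)), tables = tables,
       profiles = profiles, coiMap = coiMap, refAlns = refAlns)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full typing workflow and write a summary
#'
#' Chains signature discovery, query typing, statistical-parsimony
#' networks with biogeography, and the NJ monophyly/bootstrap check on the
#' concatenated SSU+ITS alignment.  Writes \code{signatures.tsv},
#' \code{calls.tsv}, per-marker network nodes/edges TSVs,
#' \code{summary.json} and the resolved configuration
#' (\code{config.json}) into `outDir`.
#'
#' @param alignments Named list of [MarkerAlignment-class] objects
#'   (\code{SSU}, \code{ITS}, \code{COI_nt}; any subset with >= 1 marker).
#' @param meta Metadata data.frame.
#' @param queries Optional named list: marker to named character vector of
#'   query sequences.
#' @param outDir Output directory (created if needed).
#' @param alpha Parsimony confidence level for the connection limit.
#' @param minEvaluable Minimum covered diagnostic columns for typing.
#' @param translTable,frame COI translation options.
#' @param bootstrapReps Bootstrap replicates for the tree check (0 to
#'   skip).
#' @param networkMarker Marker whose network feeds the biogeography table
#'   (default \code{"ITS"}, falling back to the first available marker).
#' @param seed Seed for the bootstrap resampling.
#' @return Invisibly, the summary list.
#' @export
runReport <- function(alignments, meta, queries = NULL, outDir,
                      alpha = 0.95, minEvaluable = 3L, translTable = 4,
                      frame = 1L, bootstrapReps = 100L,
                      networkMarker = "ITS", seed = 1L) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  cfg <- list(markers = names(alignments), alpha = alpha,
              min_evaluable = minEvaluable, transl_table = translTable,
              frame = frame, bootstrap_reps = bootstrapReps,
              network_marker = networkMarker, seed = seed)
  jsonlite::write_json(cfg, file.path(outDir, "config.json"),
                       auto_unbox = TRUE, digits = NA)

  disc <- .stage("discover", discoverSignatures(alignments, meta,
                                                translTable, frame))
  sig <- disc$signature
  writeSignatureReport(sig, file.path(outDir, "signatures.tsv"))
  variableCounts <- vapply(disc$tables, function(t) nrow(t@entries),
                           integer(1))
  diagCounts <- lapply(disc$tables, function(t) {
    dg <- diagnosticTriples(t)
    vapply(sig@clades, function(cc) sum(dg$clade == cc), integer(1))
  })

  calls <- .stage("type", {
    if (is.null(queries) || !length(queries)) {
      data.frame(query_id = character(), marker = character(),
                 call_type = character(), final_call = character(),
                 n_evaluable = integer(), error = character(),
                 region = character())
    } else {
      do.call(rbind, lapply(names(queries), function(mk)
        batchType(queries[[mk]], sig, disc$refAlns, mk, minEvaluable,
                  meta)))
    }
  })
  utils::write.table(calls, file.path(outDir, "calls.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tally <- table(factor(calls$call_type,
                        levels = c("ASSIGNED", "AMBIGUOUS", "CONFLICT",
                                   "INSUFFICIENT", "ERROR")))

  networks <- .stage("network", {
    out <- list()
    for (mk in intersect(c("SSU", "ITS", "COI_nt"), names(alignments))) {
      aln <- alignments[[mk]]
      haps <- collapseHaplotypes(aln, meta)
      lim <- connectionLimit(comparedCharacters(aln), alpha)
      net <- buildNetwork(haps, lim)
      writeNetworkTSV(net, file.path(outDir, paste0("network_", mk)))
      out[[mk]] <- net
    }
    out
  })
  if (!networkMarker %in% names(networks))
    networkMarker <- names(networks)[1L]
  biogeo <- .stage("network", {
    net <- networks[[networkMarker]]
    part <- joinAlignmentMetadata(alignments[[networkMarker]], meta)
    summarizeBiogeography(net, part)
  })

  treecheck <- .stage("treecheck", {
    mks <- intersect(c("SSU", "ITS"), names(alignments))
    if (!length(mks)) mks <- names(alignments)[1L]
    cat <- concatenateAlignments(alignments[mks])
    part <- joinAlignmentMetadata(cat, meta)
    tree <- suppressMessages(neighborJoining(pDistance(cat)))
    mono <- checkMonophyly(tree, part)
    boot <- if (bootstrapReps > 0L)
      bootstrapSupport(cat, part, bootstrapReps, seed) else NULL
    ape::write.tree(tree, file.path(outDir, "nj_concat.nwk"))
    list(monophyly = mono, bootstrap = boot)
  })

  summary <- list(
    variable_columns = as.list(variableCounts),
    diagnostic_counts = lapply(diagCounts, as.list),
    separability = separability(sig),
    typing_tally = as.list(tally),
    network = lapply(networks, function(n) list(
      n_haplotypes = length(n@haplotypes@hapIds),
      n_edges = nrow(n@edges),
      n_components = length(unique(n@component)),
      limit_J = n@limit@limitJ)),
    europe_only = biogeo$clades$clade[biogeo$clades$europe_only],
    biogeography = biogeo$clades,
    monophyly = treecheck$monophyly,
    bootstrap = treecheck$bootstrap)
  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(summary)
}
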