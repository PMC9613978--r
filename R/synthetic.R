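## Truth-tracked synthetic data generator. Emulates the structure the
## typing workflow assumes: five clades (syngens R1..R5) with planted fixed
## per-clade substitutions, within-clade polymorphic sites, an R1+R2 shared
## pattern in the SSU, a COI open reading frame whose planted changes are
## nonsynonymous, and clade-specific geographic label distributions.

#' Simulation configuration (the reference preset by default)
#'
#' The defaults encode the study conditions the package targets: 48 records
#' in five clades sized like the reference strain set (R1: 11, R2: 12,
#' R3: 20, R4: 4, R5: 1, the last syngen being known from a single strain);
#' marker lengths SSU 1700, ITS 500, COI 600 nt; 30 variable SSU columns
#' (8 synapomorphies each for R3/R4/R5 plus 6 columns at which R1 and R2
#' share a derived state, making them inseparable by SSU alone); 23
#' variable ITS columns (4 synapomorphies per clade plus 3 within-clade
#' variable sites); and a COI reading frame whose translation carries 18
#' variable amino-acid columns of which 13 are diagnostic (3/3/3/2/2 per
#' clade; the remaining 5 are fixed states shared by a clade pair).
#' Geography: R1 and R5 are Europe-only; every other clade is guaranteed at
#' least one non-European record.
#'
#' @param clades Clade labels.
#' @param perCladeN Named integer vector of members per clade.
#' @param markerLengths Named lengths for SSU, ITS and COI_nt (COI length
#'   must be a multiple of 3).
#' @param nSynapomorphies Named list per marker (SSU, ITS, COI_aa) of named
#'   per-clade synapomorphy counts.
#' @param nWithinVariable Named counts of within-clade variable columns per
#'   marker.
#' @param sharedPairs List of `list(marker=, clades=c(a, b), n=)` entries:
#'   columns at which both clades share one derived state.
#' @param queryErrorRate Per-site substitution error applied to queries.
#' @param regionModel Named list: clade to named probability vector over
#'   [regionLevels()].
#' @param translTable NCBI translation table for the COI reading frame.
#' @param seed Integer master seed; all randomness derives from it.
#' @return A list of class \code{"SimulationConfig"}.
#' @export
#' @examples
#' cfg <- simulationConfig(seed = 42)
#' names(cfg)
simulationConfig <- function(
    clades = syngenLevels(),
    perCladeN = c(R1 = 11L, R2 = 12L, R3 = 20L, R4 = 4L, R5 = 1L),
    markerLengths = c(SSU = 1700L, ITS = 500L, COI_nt = 600L),
    nSynapomorphies = list(
      SSU = c(R1 = 0L, R2 = 0L, R3 = 8L, R4 = 8L, R5 = 8L),
      ITS = c(R1 = 4L, R2 = 4L, R3 = 4L, R4 = 4L, R5 = 4L),
      COI_aa = c(R1 = 3L, R2 = 3L, R3 = 3L, R4 = 2L, R5 = 2L)),
    nWithinVariable = c(SSU = 0L, ITS = 3L, COI_aa = 0L),
    sharedPairs = list(
      list(marker = "SSU", clades = c("R1", "R2"), n = 6L),
      list(marker = "COI_aa", clades = c("R1", "R2"), n = 3L),
      list(marker = "COI_aa", clades = c("R3", "R4"), n = 2L)),
    queryErrorRate = 0,
    regionModel = list(
      R1 = c(Europe = 1),
      R2 = c(Europe = 0.7, Asia = 0.2, Australia = 0.1),
      R3 = c(Europe = 0.3, Asia = 0.4, `North America` = 0.1,
             `South America` = 0.1, Australia = 0.1),
      R4 = c(`North America` = 0.4, `South America` = 0.3, Europe = 0.3),
      R5 = c(Europe = 1)),
    translTable = 4,
    seed = 42L) {
  cfg <- list(clades = clades, perCladeN = perCladeN,
              markerLengths = markerLengths,
              nSynapomorphies = nSynapomorphies,
              nWithinVariable = nWithinVariable, sharedPairs = sharedPairs,
              queryErrorRate = queryErrorRate, regionModel = regionModel,
              translTable = translTable, seed = as.integer(seed))
  class(cfg) <- "SimulationConfig"
  .validateSimulationConfig(cfg)
  cfg
}

#' @rdname simulationConfig
#' @export
referencePreset <- function(seed = 42L) simulationConfig(seed = seed)

.validateSimulationConfig <- function(cfg) {
  stopifnot(length(cfg$clades) >= 2L,
            all(cfg$clades %in% names(cfg$perCladeN)),
            all(cfg$perCladeN >= 1L),
            cfg$markerLengths[["COI_nt"]] %% 3L == 0L)
  for (mk in names(cfg$nSynapomorphies)) {
    len <- if (mk == "COI_aa") cfg$markerLengths[["COI_nt"]] %/% 3L
           else cfg$markerLengths[[mk]]
    shared <- sum(vapply(cfg$sharedPairs,
                         function(sp) if (sp$marker == mk) sp$n else 0L,
                         numeric(1)))
    within <- if (mk %in% names(cfg$nWithinVariable))
      cfg$nWithinVariable[[mk]] else 0L
    tot <- sum(cfg$nSynapomorphies[[mk]]) + shared + within
    if (tot > len)
      stop(sprintf("infeasible config: %d planted columns exceed %s length %d",
                   tot, mk, len))
  }
  for (sp in cfg$sharedPairs)
    stopifnot(length(sp$clades) == 2L, all(sp$clades %in% cfg$clades))
  wv <- names(cfg$nWithinVariable)[cfg$nWithinVariable > 0L]
  if (length(wv) && !any(cfg$perCladeN >= 2L))
    stop("within-clade variable sites require a clade with >= 2 members")
  invisible(TRUE)
}

## deterministic per-marker substream seed below 2^31
.substreamSeed <- function(seed, k) {
  as.integer((as.numeric(seed) + k * 1000003) %% 2147483647)
}

.sampleDerived <- function(root) sample(setdiff(.NT_UNAMBIGUOUS, root), 1L)

## plant one nucleotide marker; returns seqs matrix + truth pieces
.simulateNtMarker <- function(mk, cfg, ids, cladeOf) {
  len <- cfg$markerLengths[[mk]]
  root <- sample(.NT_UNAMBIGUOUS, len, replace = TRUE)
  syn <- cfg$nSynapomorphies[[mk]]
  shared <- Filter(function(sp) sp$marker == mk, cfg$sharedPairs)
  nWithin <- if (mk %in% names(cfg$nWithinVariable))
    cfg$nWithinVariable[[mk]] else 0L
  nShared <- sum(vapply(shared, function(sp) sp$n, numeric(1)))
  cols <- sample.int(len, sum(syn) + nShared + nWithin)

  m <- matrix(rep(root, each = length(ids)), nrow = length(ids),
              dimnames = list(ids, NULL))
  at <- 0L
  synTruth <- list(); sharedTruth <- list(); withinTruth <- list()
  for (cc in cfg$clades) {
    k <- syn[[cc]]
    if (is.null(k) || k == 0L) next
    ccCols <- cols[at + seq_len(k)]; at <- at + k
    for (j in ccCols) {
      st <- .sampleDerived(root[j])
      m[cladeOf[ids] == cc, j] <- st
      synTruth[[length(synTruth) + 1L]] <-
        data.frame(marker = mk, clade = cc, column = j, state = st)
    }
  }
  for (sp in shared) {
    spCols <- cols[at + seq_len(sp$n)]; at <- at + sp$n
    for (j in spCols) {
      st <- .sampleDerived(root[j])
      m[cladeOf[ids] %in% sp$clades, j] <- st
      sharedTruth[[length(sharedTruth) + 1L]] <-
        data.frame(marker = mk, clades = paste(sp$clades, collapse = ","),
                   column = j, state = st)
    }
  }
  if (nWithin > 0L) {
    eligible <- names(cfg$perCladeN)[cfg$perCladeN >= 2L]
    wCols <- cols[at + seq_len(nWithin)]; at <- at + nWithin
    for (i in seq_along(wCols)) {
      j <- wCols[i]
      cc <- eligible[((i - 1L) %% length(eligible)) + 1L]
      mem <- ids[cladeOf[ids] == cc]
      kSub <- sample.int(length(mem) - 1L, 1L)
      pick <- sample(mem, kSub)
      st <- .sampleDerived(root[j])
      m[pick, j] <- st
      withinTruth[[length(withinTruth) + 1L]] <-
        data.frame(marker = mk, clade = cc, column = j, alt_state = st)
    }
  }
  list(m = m,
       synapomorphies = if (length(synTruth)) do.call(rbind, synTruth),
       shared = if (length(sharedTruth)) do.call(rbind, sharedTruth),
       within = if (length(withinTruth)) do.call(rbind, withinTruth))
}

## plant the COI reading frame; synapomorphies are amino-acid level and
## nonsynonymous by construction
.simulateCoiMarker <- function(cfg, ids, cladeOf) {
  code <- geneticCode(cfg$translTable)
  aaLen <- cfg$markerLengths[["COI_nt"]] %/% 3L
  codons <- names(code$codons)
  sense <- codons[code$codons != "*"]
  rootCodons <- sample(sense, aaLen, replace = TRUE)
  rootAA <- unname(code$codons[rootCodons])

  syn <- cfg$nSynapomorphies[["COI_aa"]]
  shared <- Filter(function(sp) sp$marker == "COI_aa", cfg$sharedPairs)
  nShared <- sum(vapply(shared, function(sp) sp$n, numeric(1)))
  cols <- sample.int(aaLen, sum(syn) + nShared)

  codonMat <- matrix(rep(rootCodons, each = length(ids)),
                     nrow = length(ids), dimnames = list(ids, NULL))
  derivedCodon <- function(j) {
    alt <- sense[code$codons[sense] != rootAA[j]]
    sample(alt, 1L)
  }
  at <- 0L
  synTruth <- list(); sharedTruth <- list()
  for (cc in cfg$clades) {
    k <- syn[[cc]]
    if (is.null(k) || k == 0L) next
    ccCols <- cols[at + seq_len(k)]; at <- at + k
    for (j in ccCols) {
      cd <- derivedCodon(j)
      codonMat[cladeOf[ids] == cc, j] <- cd
      synTruth[[length(synTruth) + 1L]] <-
        data.frame(marker = "COI_aa", clade = cc, column = j,
                   state = unname(code$codons[cd]))
    }
  }
  for (sp in shared) {
    spCols <- cols[at + seq_len(sp$n)]; at <- at + sp$n
    for (j in spCols) {
      cd <- derivedCodon(j)
      codonMat[cladeOf[ids] %in% sp$clades, j] <- cd
      sharedTruth[[length(sharedTruth) + 1L]] <-
        data.frame(marker = "COI_aa",
                   clades = paste(sp$clades, collapse = ","),
                   column = j, state = unname(code$codons[cd]))
    }
  }
  seqs <- apply(codonMat, 1L, paste, collapse = "")
  list(seqs = seqs,
       synapomorphies = if (length(synTruth)) do.call(rbind, synTruth),
       shared = if (length(sharedTruth)) do.call(rbind, sharedTruth))
}

#' Simulate a truth-tracked syngen dataset
#'
#' Draws a random root sequence per marker, applies the configured planted
#' substitutions (per-clade fixed synapomorphies, shared-pair states,
#' within-clade polymorphic sites), generates COI as an open reading frame
#' with no internal stop codons whose planted changes are nonsynonymous
#' under the configured genetic code, and samples geographic regions from
#' the per-clade region model (Europe-only clades draw only Europe; every
#' other clade is guaranteed at least one non-European member, so the
#' planted biogeography holds for every seed).  All randomness derives from
#' `cfg$seed` through deterministic per-marker substreams; the caller's
#' random-number state is untouched.
#'
#' @param cfg A configuration from [simulationConfig()] / [referencePreset()].
#' @return A list with elements \code{alignments} (named list of
#'   [MarkerAlignment-class]: SSU, ITS, COI_nt), \code{meta} (metadata
#'   data.frame), \code{truth} (planted ground truth: \code{cladeOf},
#'   \code{regionOf}, \code{synapomorphies}, \code{shared}, \code{within},
#'   \code{expectedCounts}, \code{europeOnly}) and \code{config}.
#' @export
#' @examples
#' sim <- simulateSyngens(referencePreset(seed = 1))
#' sim$truth$expectedCounts
simulateSyngens <- function(cfg = referencePreset()) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  .validateSimulationConfig(cfg)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))

  ids <- unlist(lapply(cfg$clades, function(cc)
    sprintf("%s-%02d", cc, seq_len(cfg$perCladeN[[cc]]))), use.names = FALSE)
  cladeOf <- stats::setNames(rep(cfg$clades, cfg$perCladeN[cfg$clades]), ids)

  alignments <- list(); synTruth <- list(); sharedTruth <- list()
  withinTruth <- list()
  for (mk in c("SSU", "ITS")) {
    set.seed(.substreamSeed(cfg$seed, match(mk, markerLevels())))
    sim <- .simulateNtMarker(mk, cfg, ids, cladeOf)
    alignments[[mk]] <- MarkerAlignment(
      ids, apply(sim$m, 1L, paste, collapse = ""), mk)
    synTruth[[mk]] <- sim$synapomorphies
    sharedTruth[[mk]] <- sim$shared
    withinTruth[[mk]] <- sim$within
  }
  set.seed(.substreamSeed(cfg$seed, match("COI_nt", markerLevels())))
  coi <- .simulateCoiMarker(cfg, ids, cladeOf)
  alignments[["COI_nt"]] <- MarkerAlignment(ids, coi$seqs, "COI_nt")
  synTruth[["COI_aa"]] <- coi$synapomorphies
  sharedTruth[["COI_aa"]] <- coi$shared

  ## geography
  set.seed(.substreamSeed(cfg$seed, 97L))
  europeOnly <- names(cfg$regionModel)[vapply(cfg$regionModel, function(p)
    identical(names(p), "Europe"), logical(1))]
  regionOf <- stats::setNames(character(length(ids)), ids)
  for (cc in cfg$clades) {
    mem <- ids[cladeOf == cc]
    p <- cfg$regionModel[[cc]]
    if (is.null(p)) p <- c(UNKNOWN = 1)
    draws <- sample(names(p), length(mem), replace = TRUE, prob = p)
    if (!(cc %in% europeOnly) && all(draws == "Europe")) {
      nonEu <- names(p)[names(p) != "Europe"]
      draws[length(draws)] <- nonEu[which.max(p[nonEu])]
    }
    regionOf[mem] <- draws
  }
  endo <- c(R1 = "Mcon", R2 = "Mcon", R3 = "Cvar", R4 = "Cvar", R5 = "Cvar")
  meta <- data.frame(id = ids, syngen = unname(cladeOf[ids]),
                     region = unname(regionOf[ids]), strain = ids,
                     endosymbiont = unname(
                       ifelse(cladeOf[ids] %in% names(endo),
                              endo[cladeOf[ids]], "UNKNOWN")))

  bindOrNull <- function(lst) {
    lst <- Filter(Negate(is.null), lst)
    if (length(lst)) do.call(rbind, lst) else NULL
  }
  syn <- bindOrNull(synTruth); shr <- bindOrNull(sharedTruth)
  wth <- bindOrNull(withinTruth)
  countsFor <- function(mk) {
    s <- if (!is.null(syn)) sum(syn$marker == mk) else 0L
    h <- if (!is.null(shr)) sum(shr$marker == mk) else 0L
    w <- if (!is.null(wth)) sum(wth$marker == mk) else 0L
    data.frame(marker = mk, variable = s + h + w, synapomorphy = s,
               shared = h, within = w)
  }
  expected <- do.call(rbind, lapply(c("SSU", "ITS", "COI_aa"), countsFor))
  truth <- list(cladeOf = cladeOf, regionOf = regionOf,
                synapomorphies = syn, shared = shr, within = wth,
                expectedCounts = expected, europeOnly = europeOnly)
  list(alignments = alignments, meta = meta, truth = truth, config = cfg)
}

#' Write a simulated dataset to a directory
#'
#' Emits \code{ssu.fasta}, \code{its.fasta}, \code{coi.fasta},
#' \code{meta.tsv} and \code{truth.json}.
#'
#' @param sim Result of [simulateSyngens()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeAlignment(sim$alignments$SSU, file.path(dir, "ssu.fasta"))
  writeAlignment(sim$alignments$ITS, file.path(dir, "its.fasta"))
  writeAlignment(sim$alignments$COI_nt, file.path(dir, "coi.fasta"))
  writeMetadata(sim$meta, file.path(dir, "meta.tsv"))
  truth <- sim$truth
  truth$cladeOf <- as.list(truth$cladeOf)
  truth$regionOf <- as.list(truth$regionOf)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Derive typing queries from a simulated dataset
#'
#' Samples records of one marker, strips gaps, optionally restricts them to
#' a fragment window, and applies independent per-site substitution errors.
#' Truth labels are emitted alongside for accuracy scoring.
#'
#' @param sim Result of [simulateSyngens()].
#' @param marker \code{"SSU"}, \code{"ITS"} or \code{"COI_nt"}.
#' @param n Number of queries (default: every record).
#' @param errorRate Per-site substitution probability (default: the
#'   configured `queryErrorRate`).
#' @param fragment NULL for full-length queries, a fixed
#'   \code{c(start, length)} window, or
#'   \code{list(start_range = c(a, b), length_range = c(c, d))} to sample a
#'   window per query.
#' @param seed Integer seed for sampling and errors.
#' @return A list with \code{queries} (named character vector; query ids
#'   are \code{q_<record id>}) and \code{truth} (data.frame
#'   \code{query_id}, \code{source_id}, \code{clade}).
#' @export
makeQueries <- function(sim, marker, n = NULL, errorRate = NULL,
                        fragment = NULL, seed = 1L) {
  aln <- sim$alignments[[marker]]
  if (is.null(aln)) stop("no such marker in simulation: ", marker)
  if (is.null(errorRate)) errorRate <- sim$config$queryErrorRate
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  ids <- recordIds(aln)
  if (!is.null(n)) ids <- sample(ids, min(n, length(ids)))
  seqs <- gsub("-", "", sequences(aln)[ids], fixed = TRUE)
  out <- character(length(ids))
  for (i in seq_along(ids)) {
    s <- seqs[[i]]
    if (!is.null(fragment)) {
      win <- if (is.list(fragment)) {
        st <- sample(fragment$start_range[1]:fragment$start_range[2], 1L)
        ln <- sample(fragment$length_range[1]:fragment$length_range[2], 1L)
        c(st, ln)
      } else fragment
      s <- substr(s, win[1], min(nchar(s), win[1] + win[2] - 1L))
    }
    if (errorRate > 0) {
      ch <- strsplit(s, "")[[1]]
      hit <- which(stats::runif(length(ch)) < errorRate & ch %in% .NT_UNAMBIGUOUS)
      for (j in hit) ch[j] <- sample(setdiff(.NT_UNAMBIGUOUS, ch[j]), 1L)
      s <- paste(ch, collapse = "")
    }
    out[i] <- s
  }
  qids <- paste0("q_", ids)
  list(queries = stats::setNames(out, qids),
       truth = data.frame(query_id = qids, source_id = ids,
                          clade = unname(sim$truth$cladeOf[ids])))
}
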