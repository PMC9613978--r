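## Haplotype collapsing and statistical-parsimony (TCS) networks with
## geographic annotation.

#' Collapse alignment records into haplotypes
#'
#' Under \code{missingPolicy = "strict"} records merge only when their
#' aligned sequences are identical as strings.  Under \code{"infer"},
#' records merge when they are identical over every column that is
#' non-missing in both members of every compared pair; because that
#' relation is not transitive, groups are required to be cliques and are
#' built by deterministic first-fit in record order (a record joins the
#' first existing haplotype it is compatible with every member of).
#' The representative is the member with fewest missing characters, ties
#' broken by lexicographically smallest id.
#'
#' @param aln A [MarkerAlignment-class].
#' @param meta Optional metadata data.frame (columns \code{id},
#'   \code{region}); records absent from it get region \code{"UNKNOWN"}.
#' @param missingPolicy \code{"strict"} or \code{"infer"}.
#' @return A [HaplotypeSet-class].
#' @export
collapseHaplotypes <- function(aln, meta = NULL,
                               missingPolicy = c("strict", "infer")) {
  missingPolicy <- match.arg(missingPolicy)
  stopifnot(is(aln, "MarkerAlignment"))
  m <- seqMatrix(aln)
  miss <- matrix(.isMissingState(m, aln@marker), nrow = nrow(m))
  compatible <- function(i, k) {
    ok <- !miss[i, ] & !miss[k, ]
    all(m[i, ok] == m[k, ok])
  }
  groups <- list()
  for (i in seq_len(nrow(m))) {
    placed <- FALSE
    for (g in seq_along(groups)) {
      mem <- groups[[g]]
      fits <- if (missingPolicy == "strict")
        aln@seqs[i] == aln@seqs[mem[1L]]
      else all(vapply(mem, function(k) compatible(i, k), logical(1)))
      if (fits) { groups[[g]] <- c(mem, i); placed <- TRUE; break }
    }
    if (!placed) groups[[length(groups) + 1L]] <- i
  }
  nMissPer <- rowSums(miss)
  reps <- vapply(groups, function(mem) {
    best <- mem[order(nMissPer[mem], aln@ids[mem])][1L]
    aln@seqs[best]
  }, character(1))
  members <- lapply(groups, function(mem) aln@ids[mem])

  regions <- stats::setNames(rep("UNKNOWN", length(aln@ids)), aln@ids)
  if (!is.null(meta)) {
    hit <- match(aln@ids, meta$id)
    regions[!is.na(hit)] <- meta$region[hit[!is.na(hit)]]
  }
  rc <- t(vapply(members, function(mem) {
    tabulate(factor(regions[mem], levels = regionLevels()),
             nbins = length(regionLevels()))
  }, integer(length(regionLevels()))))
  colnames(rc) <- regionLevels()
  rownames(rc) <- paste0("H", seq_along(groups))
  new("HaplotypeSet", marker = aln@marker,
      hapIds = paste0("H", seq_along(groups)),
      representative = reps, members = members, regionCounts = rc,
      memberRegions = regions)
}

#' Mutational steps between two haplotype representatives
#'
#' Hamming distance over the columns that are non-missing in both
#' sequences; gap or ambiguity columns are excluded (a gap never counts as
#' a step under the default policy).
#'
#' @param seq1,seq2 Representative sequence strings of equal length.
#' @param marker Marker name (controls the missing-state alphabet).
#' @return Integer number of differing shared columns.
#' @export
pairwiseSteps <- function(seq1, seq2, marker = "ITS") {
  a <- strsplit(toupper(seq1), "")[[1]]
  b <- strsplit(toupper(seq2), "")[[1]]
  if (length(a) != length(b)) stop("representatives differ in length")
  ok <- !.isMissingState(a, marker) & !.isMissingState(b, marker)
  sum(a[ok] != b[ok])
}

#' No-homoplasy (parsimony) probability of a j-step connection
#'
#' Direct evaluation of the statistical-parsimony probability underlying
#' the TCS method: under the coalescent, the number of mutations a site
#' experiences between two sequences is geometric with parameter q, and
#' state changes follow the Jukes-Cantor model, so the expected fraction of
#' differing sites is p(q) = q / (1 + q/3).  Given two haplotypes that
#' differ at j of L compared characters, q is estimated by method of
#' moments from j/L and P_j is the probability that every differing site
#' experienced exactly one mutation and every identical site none -- i.e.
#' that the j observed steps are the true, homoplasy-free mutational path.
#' Divergence beyond the Jukes-Cantor saturation point (j/L >= 3/4) has no
#' admissible single-hit explanation and gets probability 0.
#'
#' @param j Number of observed differences (0..L).
#' @param L Number of compared characters.
#' @return P_j in `[0, 1]` (P_0 = 1), computed in log space.
#' @export
#' @examples
#' parsimonyProbability(1, 600)
parsimonyProbability <- function(j, L) {
  stopifnot(L >= 1, j >= 0, j <= L)
  if (j == 0) return(1)
  p <- j / L
  if (p >= 0.75) return(0)
  q <- 3 * p / (3 - p)            # inverse of p(q) = q / (1 + q/3)
  .noHomoplasyProb(j, L, q)
}

## P(every differing site had exactly one hit, every identical site none)
## for explicit geometric parameter q, in log space
.noHomoplasyProb <- function(j, L, q) {
  p <- q / (1 + q / 3)            # expected per-site divergence under JC
  logSingle <- log1p(-q) + log(q) - log(p)
  logZero <- log1p(-q) - log1p(-p)
  exp(j * logSingle + (L - j) * logZero)
}

#' Statistical-parsimony connection limit
#'
#' The largest number of mutational steps J such that the no-homoplasy
#' probability [parsimonyProbability()] still exceeds `alpha`; haplotype
#' pairs further apart than J steps are not connected (the 95 % criterion
#' of the TCS method).
#'
#' @param L Number of compared characters (>= 1).
#' @param alpha Parsimony confidence level in (0, 1); default 0.95.
#' @return A [ConnectionLimit-class].
#' @export
#' @examples
#' connectionLimit(600)
connectionLimit <- function(L, alpha = 0.95) {
  L <- as.integer(L)
  if (is.na(L) || L < 1L) stop("L must be an integer >= 1")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie strictly between 0 and 1")
  probs <- vapply(seq_len(L), parsimonyProbability, numeric(1), L = L)
  ok <- probs > alpha
  limit <- if (any(ok)) max(which(ok)) else 0L
  new("ConnectionLimit", L = L, alpha = alpha, limitJ = as.integer(limit),
      probs = probs)
}

#' Default number of compared characters for the connection limit
#'
#' The columns considered "compared" are those non-missing in at least
#' `coverage` of the records (default 90 %), not the raw alignment length.
#'
#' @param aln A [MarkerAlignment-class].
#' @param coverage Minimum fraction of non-missing records per column.
#' @return Integer count of compared columns.
#' @export
comparedCharacters <- function(aln, coverage = 0.9) {
  m <- seqMatrix(aln)
  miss <- matrix(.isMissingState(m, aln@marker), nrow = nrow(m))
  sum(colMeans(!miss) >= coverage)
}

#' Build a statistical-parsimony haplotype network
#'
#' Candidate edges (pairs at most `limitJ` steps apart) are added in
#' non-decreasing step order.  Within one step value, every candidate edge
#' joining two components that were distinct before the step value started
#' is retained -- equal-step alternatives therefore produce reticulations
#' -- while equal-step edges internal to an already-connected component are
#' dropped.  The result is deterministic and independent of haplotype
#' input order up to haplotype ids.
#'
#' @param haps A [HaplotypeSet-class].
#' @param limit A [ConnectionLimit-class] (e.g. from [connectionLimit()]).
#' @return A [HaplotypeNetwork-class].
#' @export
buildNetwork <- function(haps, limit) {
  stopifnot(is(haps, "HaplotypeSet"), is(limit, "ConnectionLimit"))
  n <- length(haps@hapIds)
  edges <- data.frame(from = character(), to = character(),
                      steps = integer())
  comp <- seq_len(n)
  if (n >= 2L) {
    cand <- list()
    for (i in seq_len(n - 1L)) for (k in (i + 1L):n) {
      s <- pairwiseSteps(haps@representative[i], haps@representative[k],
                         haps@marker)
      if (s <= limit@limitJ)
        cand[[length(cand) + 1L]] <- c(i, k, s)
    }
    if (length(cand)) {
      cand <- do.call(rbind, cand)
      cand <- cand[order(cand[, 3], cand[, 1], cand[, 2]), , drop = FALSE]
      keep <- logical(nrow(cand))
      for (s in sort(unique(cand[, 3]))) {
        snapshot <- comp
        rows <- which(cand[, 3] == s)
        for (r in rows) {
          i <- cand[r, 1]; k <- cand[r, 2]
          if (snapshot[i] != snapshot[k]) keep[r] <- TRUE
        }
        for (r in rows[keep[rows]]) {        # union after the snapshot
          ci <- comp[cand[r, 1]]; ck <- comp[cand[r, 2]]
          if (ci != ck) comp[comp == ck] <- ci
        }
      }
      kept <- cand[keep, , drop = FALSE]
      edges <- data.frame(from = haps@hapIds[kept[, 1]],
                          to = haps@hapIds[kept[, 2]],
                          steps = as.integer(kept[, 3]))
    }
  }
  comp <- match(comp, unique(comp))          # canonical component ids
  new("HaplotypeNetwork", haplotypes = haps, edges = edges,
      component = as.integer(comp), limit = limit)
}

#' Summarize the biogeography of a haplotype network
#'
#' Per clade: the set of regions its records were collected from and a
#' Europe-only flag; per network component: the clade composition.
#'
#' @param net A [HaplotypeNetwork-class].
#' @param partition A [CladePartition-class] labelling the member records.
#' @return A list of two data.frames: \code{clades} (columns \code{clade},
#'   \code{regions}, \code{europe_only}) and \code{components} (columns
#'   \code{component}, \code{n_haplotypes}, \code{clades}).
#' @export
summarizeBiogeography <- function(net, partition) {
  stopifnot(is(net, "HaplotypeNetwork"), is(partition, "CladePartition"))
  haps <- net@haplotypes
  cl <- cladeOf(partition)
  memberClades <- lapply(haps@members, function(mem) {
    x <- cl[mem]; x[is.na(x)] <- "UNKNOWN"; x
  })
  clades <- cladeLevels(partition)
  rows <- lapply(clades, function(cc) {
    regs <- character()
    for (h in seq_along(haps@members)) {
      mem <- haps@members[[h]][memberClades[[h]] == cc]
      regs <- c(regs, haps@memberRegions[mem])
    }
    regs <- sort(unique(regs))
    data.frame(clade = cc, regions = paste(regs, collapse = ","),
               europe_only = length(regs) > 0L && identical(regs, "Europe"))
  })
  cladeTab <- do.call(rbind, rows)

  compTab <- do.call(rbind, lapply(sort(unique(net@component)), function(g) {
    hs <- which(net@component == g)
    cls <- sort(unique(unlist(memberClades[hs], use.names = FALSE)))
    data.frame(component = g, n_haplotypes = length(hs),
               clades = paste(cls, collapse = ","))
  }))
  list(clades = cladeTab, components = compTab)
}

#' Write a haplotype network as nodes/edges TSV files
#'
#' @param net A [HaplotypeNetwork-class].
#' @param prefix Output path prefix; writes \code{<prefix>_nodes.tsv} and
#'   \code{<prefix>_edges.tsv}.
#' @return Invisibly, the two paths.
#' @export
writeNetworkTSV <- function(net, prefix) {
  haps <- net@haplotypes
  nodes <- data.frame(hap_id = haps@hapIds, freq = lengths(haps@members),
                      component = net@component,
                      members = vapply(haps@members, paste, character(1),
                                       collapse = ","))
  rc <- haps@regionCounts
  for (r in colnames(rc)) nodes[[gsub(" ", "_", r)]] <- rc[, r]
  np <- paste0(prefix, "_nodes.tsv"); ep <- paste0(prefix, "_edges.tsv")
  utils::write.table(nodes, np, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(net@edges, ep, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(np, ep))
}

#' Export a haplotype network as GraphML
#'
#' Nodes carry \code{freq} and a JSON \code{region_counts} attribute; edges
#' carry \code{steps}.
#'
#' @param net A [HaplotypeNetwork-class].
#' @param path Output GraphML path.
#' @return Invisibly, `path`.
#' @export
writeNetworkGraphML <- function(net, path) {
  g <- asIgraph(net)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Convert a haplotype network to an igraph object
#'
#' @param net A [HaplotypeNetwork-class].
#' @return An undirected igraph graph with node attributes \code{freq} and
#'   \code{region_counts} (JSON) and edge attribute \code{steps}.
#' @export
asIgraph <- function(net) {
  haps <- net@haplotypes
  rcJson <- vapply(seq_along(haps@hapIds), function(i) {
    as.character(jsonlite::toJSON(as.list(haps@regionCounts[i, ]),
                                  auto_unbox = TRUE))
  }, character(1))
  g <- igraph::make_empty_graph(n = length(haps@hapIds), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = haps@hapIds)
  g <- igraph::set_vertex_attr(g, "freq", value = lengths(haps@members))
  g <- igraph::set_vertex_attr(g, "region_counts", value = rcJson)
  if (nrow(net@edges)) {
    g <- igraph::add_edges(g, rbind(match(net@edges$from, haps@hapIds),
                                    match(net@edges$to, haps@hapIds)))
    g <- igraph::set_edge_attr(g, "steps", value = net@edges$steps)
  }
  g
}
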