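## Independent oracles and fixture builders used across the suite.
## Every oracle re-derives its answer by direct enumeration or a closed
## form, independently of the implementation path it checks.

## ---- tiny alignment builders ------------------------------------------------

toyAlignment <- function(seqs, marker = "ITS", ids = NULL) {
  if (is.null(ids)) ids <- paste0("s", seq_along(seqs))
  MarkerAlignment(ids, seqs, marker)
}

toyPartition <- function(aln, clades) {
  CladePartition(recordIds(aln), clades)
}

## random small alignment + partition for the randomized corpora
randomCase <- function(nMax = 6L, colMax = 20L, withMissing = TRUE,
                       cladePool = c("R1", "R2", "R3")) {
  n <- sample(2:nMax, 1L)
  L <- sample(2:colMax, 1L)
  pool <- c("A", "C", "G", "T")
  if (withMissing) pool <- c(pool, "-", "N")
  m <- matrix(sample(pool, n * L, replace = TRUE,
                     prob = if (withMissing)
                       c(rep(0.22, 4), 0.06, 0.06) else rep(0.25, 4)),
              nrow = n)
  nClades <- sample(2:min(3L, n), 1L)
  clades <- sample(cladePool, nClades)
  lab <- c(clades, sample(c(clades, "UNKNOWN"), n - nClades, replace = TRUE))
  aln <- toyAlignment(apply(m, 1L, paste, collapse = ""))
  list(aln = aln, partition = toyPartition(aln, lab))
}

## ---- diagnostics oracle -----------------------------------------------------

## Direct-enumeration synapomorphy checker: tests the definition over every
## (clade, state, column) triple on the raw character matrix.
oracleClassify <- function(aln, partition, marker = "ITS") {
  m <- do.call(rbind, strsplit(unname(sequences(aln)), ""))
  cl <- unname(cladeOf(partition))
  missing <- function(ch) !(ch %in% c("A", "C", "G", "T"))
  labelled <- setdiff(unique(cl), "UNKNOWN")
  out <- list()
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    obs <- col[!missing(col)]
    if (length(unique(obs)) < 2L) next
    diag <- character()
    for (cc in labelled) for (s in c("A", "C", "G", "T")) {
      inside <- col[cl == cc]; inside <- inside[!missing(inside)]
      outside <- col[cl != cc]; outside <- outside[!missing(outside)]
      if (length(inside) >= 1L && all(inside == s) && !(s %in% outside))
        diag <- c(diag, cc)
    }
    diag <- unique(diag)
    within <- FALSE
    for (cc in labelled) {
      inside <- col[cl == cc]; inside <- inside[!missing(inside)]
      if (length(unique(inside)) >= 2L) within <- TRUE
    }
    cat <- if (length(diag)) "SYNAPOMORPHY"
           else if (within) "WITHIN_CLADE_VARIABLE" else "OTHER_VARIABLE"
    out[[length(out) + 1L]] <- data.frame(
      column = j, category = cat,
      diagnostic_for = paste(sort(diag), collapse = ","))
  }
  if (!length(out))
    return(data.frame(column = integer(), category = character(),
                      diagnostic_for = character()))
  do.call(rbind, out)
}

## ---- TCS parsimony-probability oracle ---------------------------------------

## q solved numerically (uniroot) instead of by closed form, probability by
## direct per-site multiplication instead of log space
oracleConnectionLimit <- function(L, alpha = 0.95) {
  probJ <- function(j) {
    if (j == 0) return(1)
    p <- j / L
    if (p >= 0.75) return(0)
    q <- stats::uniroot(function(q) q / (1 + q / 3) - p,
                        c(1e-12, 1 - 1e-12), tol = 1e-14)$root
    single <- (1 - q) * q / p
    zero <- (1 - q) / (1 - p)
    prod(c(rep(single, j), rep(zero, L - j)))
  }
  j <- 0L
  while (j < L && probJ(j + 1L) > alpha) j <- j + 1L
  j
}

## ---- network oracles --------------------------------------------------------

## component partition by boolean transitive closure over pairs <= limit
oracleComponents <- function(stepsMat, limitJ) {
  n <- nrow(stepsMat)
  adj <- stepsMat <= limitJ
  diag(adj) <- TRUE
  repeat {
    nxt <- adj | (adj %*% adj > 0)
    if (identical(nxt, adj)) break
    adj <- nxt
  }
  comp <- integer(n); g <- 0L
  for (i in seq_len(n)) if (comp[i] == 0L) {
    g <- g + 1L
    comp[adj[i, ]] <- g
  }
  comp
}

## ---- tree oracles -----------------------------------------------------------

## random unrooted binary tree topology over n taxa with positive branch
## lengths; returns the ape phylo and its exact additive distance matrix
randomAdditiveCase <- function(n = 6L) {
  tr <- ape::rtree(n, rooted = FALSE, br = runif, min = 0.05, max = 0.5)
  D <- ape::cophenetic.phylo(tr)
  D <- D[order(rownames(D)), order(colnames(D))]
  list(tree = tr, D = D)
}

## brute-force monophyly: drop each internal edge of the tree (as a graph)
## and read the two leaf sets of the resulting components
oracleMonophyly <- function(tree, partition) {
  cl <- cladeOf(partition)
  labelled <- names(cl)[cl != "UNKNOWN"]
  g <- igraph::graph_from_edgelist(
    matrix(as.character(tree$edge), ncol = 2), directed = FALSE)
  splitSets <- list()
  for (e in seq_len(nrow(tree$edge))) {
    g2 <- igraph::delete_edges(g, e)
    memb <- igraph::components(g2)$membership
    for (side in 1:2) {
      leafIdx <- as.integer(names(memb)[memb == side])
      leaves <- tree$tip.label[leafIdx[leafIdx <= length(tree$tip.label)]]
      splitSets[[length(splitSets) + 1L]] <-
        sort(intersect(leaves, labelled))
    }
  }
  clades <- cladeLevels(partition)
  vapply(clades, function(cc) {
    mem <- sort(names(cl)[cl == cc])
    if (length(mem) <= 1L ||
        length(mem) == length(intersect(tree$tip.label, labelled)))
      return(TRUE)
    any(vapply(splitSets, identical, logical(1), mem))
  }, logical(1))
}

## ---- shared randomized corpora ---------------------------------------------
## Parameterized so unit tests run a quick pass and the acceptance suite the
## full-size corpus. Expectations fire inside the calling test_that() block.

runDiagnosticsCorpus <- function(nCases, seed) {
  set.seed(seed)
  for (case in seq_len(nCases)) {
    rc <- randomCase()
    labelled <- setdiff(unique(cladeOf(rc$partition)), "UNKNOWN")
    if (length(labelled) < 2L) next
    prof <- findVariableColumns(rc$aln, rc$partition)
    want <- oracleClassify(rc$aln, rc$partition)
    got <- classifyColumns(prof, rc$partition)@entries
    expect_identical(got$column, want$column)
    expect_identical(got$category, want$category)
    syn <- got$category == "SYNAPOMORPHY"
    expect_identical(vapply(strsplit(got$diagnostic_for[syn], ","),
                            function(x) paste(sort(x), collapse = ","),
                            character(1)),
                     want$diagnostic_for[syn])
  }
}

runNetworkCorpus <- function(nCases, seed) {
  set.seed(seed)
  for (case in seq_len(nCases)) {
    n <- sample(2:8, 1L)
    len <- 12L
    seqs <- unique(vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
            collapse = ""), character(1)))
    aln <- toyAlignment(seqs, ids = paste0("h", seq_along(seqs)))
    haps <- collapseHaplotypes(aln)
    J <- sample(0:6, 1L)
    limr <- new("ConnectionLimit", L = len, alpha = 0.95,
                limitJ = as.integer(J), probs = numeric(0))
    net <- buildNetwork(haps, limr)
    m <- length(haps)
    stepsMat <- matrix(0L, m, m)
    for (i in seq_len(m)) for (k in seq_len(m))
      stepsMat[i, k] <- pairwiseSteps(haps@representative[i],
                                      haps@representative[k])
    expect_identical(sum(hapFreq(net@haplotypes)), length(aln))
    expect_true(all(networkEdges(net)$steps <= J))
    want <- oracleComponents(stepsMat, J)
    got <- unname(networkComponents(net))
    expect_identical(as.integer(factor(got, levels = unique(got))),
                     as.integer(factor(want, levels = unique(want))))
    for (g in unique(want)) {
      nodes <- which(want == g)
      if (length(nodes) < 2L) next
      W <- stepsMat[nodes, nodes, drop = FALSE]
      W[W > J] <- 0L
      fullW <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                                   weighted = TRUE)
      mstWeight <- sum(igraph::E(igraph::mst(fullW))$weight)
      edges <- networkEdges(net)
      idx <- match(c(edges$from, edges$to), hapIds(net))
      inComp <- matrix(idx, ncol = 2)
      keepRows <- which(want[inComp[, 1]] == g & want[inComp[, 2]] == g)
      sub <- igraph::make_empty_graph(length(nodes), directed = FALSE)
      remap <- match(seq_len(m), nodes)
      if (length(keepRows)) {
        sub <- igraph::add_edges(sub, rbind(remap[inComp[keepRows, 1]],
                                            remap[inComp[keepRows, 2]]))
        sub <- igraph::set_edge_attr(sub, "weight",
                                     value = edges$steps[keepRows])
      }
      expect_true(igraph::is_connected(sub))
      expect_identical(as.integer(sum(igraph::E(igraph::mst(sub))$weight)),
                       as.integer(mstWeight))
    }
  }
}

runNJCorpus <- function(nCases, seed) {
  set.seed(seed)
  for (case in seq_len(nCases)) {
    rc <- randomAdditiveCase(6L)
    tr <- neighborJoining(rc$D)
    expect_true(as.numeric(
      ape::dist.topo(ape::unroot(tr), ape::unroot(rc$tree))) == 0)
  }
}
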