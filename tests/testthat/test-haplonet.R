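test_that("haplotype collapsing merges identical records and aggregates regions", {
  aln <- toyAlignment(rep("ACGT", 4), ids = c("a", "b", "c", "d"))
  meta <- data.frame(id = c("a", "b", "c", "d"),
                     syngen = "R1",
                     region = c("Europe", "Europe", "Europe", "Asia"))
  haps <- collapseHaplotypes(aln, meta)
  expect_length(haps, 1L)
  expect_identical(unname(hapFreq(haps)), 4L)
  expect_identical(regionCounts(haps)[1, "Europe"], 3L)
  expect_identical(regionCounts(haps)[1, "Asia"], 1L)

  two <- collapseHaplotypes(toyAlignment(c("ACGT", "ACGA")))
  expect_length(two, 2L)
})

test_that("strict vs infer policies treat missing data differently", {
  aln <- toyAlignment(c("ACGT", "ACGN"), ids = c("x", "y"))
  expect_length(collapseHaplotypes(aln, missingPolicy = "strict"), 2L)
  merged <- collapseHaplotypes(aln, missingPolicy = "infer")
  expect_length(merged, 1L)
  ## representative is the member with fewest missing characters
  expect_identical(merged@representative, "ACGT")
  ## ties break toward the lexicographically smallest id
  tie <- collapseHaplotypes(toyAlignment(c("ACGT", "ACGT"),
                                         ids = c("zz", "aa")))
  expect_identical(hapMembers(tie)[[1]], c("zz", "aa"))
  expect_identical(tie@representative, "ACGT")
})

test_that("mutational steps are Hamming over shared non-missing columns", {
  expect_identical(pairwiseSteps("ACGT", "ACGT"), 0L)
  expect_identical(pairwiseSteps("ACGT", "TCGA"), 2L)
  expect_identical(pairwiseSteps("AC-T", "ACGT"), 0L)   # gap column excluded
  expect_identical(pairwiseSteps("ANGT", "ACGA"), 1L)   # N column excluded
  expect_error(pairwiseSteps("ACG", "ACGT"), "length")
})

test_that("connection limit agrees with an independent direct evaluation", {
  for (L in c(50L, 100L, 300L, 600L, 1000L)) {
    lim <- connectionLimit(L, 0.95)
    expect_identical(lim@limitJ, oracleConnectionLimit(L, 0.95),
                     info = paste("L =", L))
  }
  ## L = 1: equal to the direct evaluation, and in {0, 1}
  l1 <- connectionLimit(1L, 0.95)
  expect_identical(l1@limitJ, oracleConnectionLimit(1L, 0.95))
  expect_true(l1@limitJ %in% c(0L, 1L))
  expect_error(connectionLimit(0), "L must be")
  expect_error(connectionLimit(100, 1), "alpha")
})

test_that("connection limit is monotone in L and alpha; tiny alpha admits
           every step on small alignments", {
  Ls <- c(10L, 50L, 200L, 600L, 1200L)
  J95 <- vapply(Ls, function(L) limitJ(connectionLimit(L, 0.95)), integer(1))
  expect_true(all(diff(J95) >= 0L))
  alphas <- c(0.5, 0.9, 0.95, 0.99)
  Ja <- vapply(alphas, function(a) limitJ(connectionLimit(600L, a)),
               integer(1))
  expect_true(all(diff(Ja) <= 0L))
  ## limiting behaviour: as alpha -> 0 every step with a positive
  ## single-hit probability becomes admissible, i.e. everything up to the
  ## Jukes-Cantor saturation bound (divergence 3/4)
  for (L in 1:6) {
    saturation <- sum(seq_len(L) / L < 0.75)
    expect_identical(limitJ(connectionLimit(L, 1e-9)), saturation)
  }
  expect_gte(limitJ(connectionLimit(600L, 1e-9)),
             limitJ(connectionLimit(600L, 0.95)))
})

test_that("the no-homoplasy probability matches Monte-Carlo simulation of
           the mutation model", {
  ## geometric number of hits per site, Jukes-Cantor state changes;
  ## condition on the observed number of differing sites
  set.seed(4242)
  L <- 6L; j <- 2L
  q <- 0.3
  nSim <- 40000L
  hits <- 0L; pars <- 0L
  for (r in seq_len(nSim)) {
    k <- stats::rgeom(L, prob = 1 - q)
    diff <- vapply(k, function(ki) {
      state <- 0L
      for (s in seq_len(ki)) state <- sample(setdiff(0:3, state), 1L)
      state != 0L
    }, logical(1))
    if (sum(diff) == j) {
      hits <- hits + 1L
      if (all(k[diff] == 1L) && all(k[!diff] == 0L)) pars <- pars + 1L
    }
  }
  mc <- pars / hits
  expect_gt(hits, 1000L)
  expect_lt(abs(mc - SyngenMarkers:::.noHomoplasyProb(j, L, q)), 0.03)
})

test_that("network construction matches the closure and MST oracles", {
  ## hand case: A-B and B-C at 1 step, A-C at 2 steps, generous limit
  haps <- collapseHaplotypes(toyAlignment(c("AAAA", "AAAT", "AATT"),
                                          ids = c("A", "B", "C")))
  lim <- new("ConnectionLimit", L = 4L, alpha = 0.95, limitJ = 10L,
             probs = numeric(0))
  net <- buildNetwork(haps, lim)
  expect_identical(nrow(networkEdges(net)), 2L)
  expect_identical(sort(networkEdges(net)$steps), c(1L, 1L))
  expect_identical(length(unique(networkComponents(net))), 1L)

  ## two clusters twelve steps apart under limit 10 stay separate
  far <- collapseHaplotypes(toyAlignment(
    c("AAAAAAAAAAAA", "AAAAAAAAAAAT", "TTTTTTTTTTTG", "TTTTTTTTTTTC")))
  netFar <- buildNetwork(far, lim)
  expect_identical(length(unique(networkComponents(netFar))), 2L)
  expect_true(all(networkEdges(netFar)$steps <= 10L))

  ## single haplotype
  one <- collapseHaplotypes(toyAlignment("ACGT"))
  net1 <- buildNetwork(one, lim)
  expect_identical(length(unique(networkComponents(net1))), 1L)
  expect_identical(nrow(networkEdges(net1)), 0L)

  runNetworkCorpus(nCases = 100, seed = 777)
})

test_that("reticulations: tied edges between distinct components are all kept,
           ties inside a component are dropped", {
  ## square: A-B = 1, C-D = 1, A-C = B-D = 2 (two tied bridges), A-D = B-C = 3
  aln <- toyAlignment(c("AAAAA", "AAAAT", "AGGAA", "AGGAT"),
                      ids = c("A", "B", "C", "D"))
  haps <- collapseHaplotypes(aln)
  lim <- new("ConnectionLimit", L = 5L, alpha = 0.95, limitJ = 5L,
             probs = numeric(0))
  net <- buildNetwork(haps, lim)
  e <- networkEdges(net)
  key <- paste(e$from, e$to)
  expect_setequal(key[e$steps == 1L], c("H1 H2", "H3 H4"))
  ## both 2-step bridges retained (reticulation), 3-step edges dropped
  expect_setequal(key[e$steps == 2L], c("H1 H3", "H2 H4"))
  expect_false(any(e$steps == 3L))
})

test_that("biogeography summaries flag Europe-only clades from planted truth", {
  sim <- simulateSyngens(referencePreset(seed = 13))
  aln <- sim$alignments$ITS
  part <- joinAlignmentMetadata(aln, sim$meta)
  haps <- collapseHaplotypes(aln, sim$meta)
  net <- buildNetwork(haps, connectionLimit(comparedCharacters(aln)))
  bio <- summarizeBiogeography(net, part)
  expect_identical(bio$clades$clade[bio$clades$europe_only],
                   sim$truth$europeOnly)
  expect_identical(bio$clades$regions[bio$clades$clade == "R1"], "Europe")
  wide <- bio$clades$regions[bio$clades$clade == "R3"]
  expect_gt(length(strsplit(wide, ",")[[1]]), 1L)
  ## region counts on nodes sum to record count
  expect_identical(sum(regionCounts(net)), length(aln))
})

test_that("network exports are well-formed", {
  sim <- simulateSyngens(referencePreset(seed = 13))
  haps <- collapseHaplotypes(sim$alignments$ITS, sim$meta)
  net <- buildNetwork(haps, connectionLimit(500L))
  pre <- withr::local_tempfile()
  paths <- writeNetworkTSV(net, pre)
  nodes <- utils::read.delim(paths[1])
  expect_identical(nrow(nodes), length(haps))
  expect_true(all(c("hap_id", "freq", "component") %in% names(nodes)))
  gml <- withr::local_tempfile(fileext = ".graphml")
  writeNetworkGraphML(net, gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_identical(as.integer(igraph::vcount(g)), length(haps))
  expect_identical(as.integer(igraph::ecount(g)), nrow(networkEdges(net)))
  rc <- jsonlite::fromJSON(igraph::vertex_attr(g, "region_counts")[1])
  expect_identical(sum(unlist(rc)), unname(hapFreq(haps)[1]))
})
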