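## A small two-clade reference used across typing tests: clade R1 and R2
## are each fixed for private states at four diagnostic columns.
refFixture <- function() {
  ##            123456789012
  r1 <- c("ACGTACGTACGT", "ACGTACGTACGT", "ACGTACGTACGT")
  r2 <- c("TCGAACGAACGA", "TCGAACGAACGA")   # differs at columns 1, 4, 8, 12
  aln <- toyAlignment(c(r1, r2), marker = "ITS",
                      ids = c("r1a", "r1b", "r1c", "r2a", "r2b"))
  part <- toyPartition(aln, c("R1", "R1", "R1", "R2", "R2"))
  sig <- combineMarkers(list(classifyColumns(
    findVariableColumns(aln, part), part)))
  list(aln = aln, part = part, sig = sig)
}

test_that("query-to-reference mapping is exact for clean and partial queries", {
  fx <- refFixture()
  ## identical to a gap-free record -> identity mapping
  mp <- mapQueryToReference("ACGTACGTACGT", fx$aln)
  expect_identical(mp$query_pos, 1:12)
  expect_identical(mp$ref_column, 1:12)
  expect_identical(attr(mp, "identity"), 1)

  ## 5' fragment maps onto the leading columns only (free end gaps)
  frag <- mapQueryToReference("ACGTAC", fx$aln)
  expect_identical(frag$ref_column, 1:6)

  ## two internal deletions skip exactly those reference columns
  ref <- toyAlignment(c("ACGTTGCAGTCA", "ACGTTGCAGTCA"), marker = "ITS")
  q <- paste(strsplit("ACGTTGCAGTCA", "")[[1]][-c(5, 9)], collapse = "")
  mp2 <- mapQueryToReference(q, ref)
  expect_identical(mp2$query_pos, 1:10)
  skipped <- setdiff(1:12, mp2$ref_column)
  ## the first deletion sits in the TT run (columns 4/5 are equivalent),
  ## the second is unambiguous
  expect_length(skipped, 2L)
  expect_true(skipped[1] %in% c(4L, 5L))
  expect_identical(skipped[2], 9L)
  expect_identical(attr(mp2, "identity"), 1)
  ## mapping is strictly increasing in both coordinates
  expect_false(is.unsorted(mp2$query_pos, strictly = TRUE))
  expect_false(is.unsorted(mp2$ref_column, strictly = TRUE))

  expect_error(mapQueryToReference("----", fx$aln), "empty query")
})

test_that("consensus excludes gap-majority columns", {
  aln <- toyAlignment(c("A-GT", "A-GA", "ACGT"))
  cons <- consensusSequence(aln)
  expect_identical(as.character(cons), "AGT")
  expect_identical(attr(cons, "columns"), c(1L, 3L, 4L))
})

test_that("typing follows the match/exclude/insufficient contract", {
  fx <- refFixture()
  refs <- list(ITS = fx$aln)

  ## clean full-length member -> assigned to its clade
  res <- typeQuery(c(q1 = "ACGTACGTACGT"), fx$sig, refs, "ITS")
  expect_identical(res$call_type, "ASSIGNED")
  expect_identical(res$final_call, "ASSIGNED(R1)")
  expect_identical(res$n_evaluable, 4L)

  ## matches R1 at three diagnostic columns but clashes at the fourth:
  ## R1 is excluded; the clash columns also exclude R2 -> CONFLICT
  res2 <- typeQuery(c(q2 = "ACGTACGTACGG"), fx$sig, refs, "ITS")
  expect_identical(res2$call_type, "CONFLICT")
  expect_true("R1" %in% res2$excluded)
  expect_identical(res2$conflicts$column[res2$conflicts$clade == "R1"], 12L)

  ## fragment covering fewer than minEvaluable diagnostic columns
  res3 <- typeQuery(c(q3 = "CGTACG"), fx$sig, refs, "ITS")   # covers cols 2-7
  expect_identical(res3$call_type, "INSUFFICIENT")

  expect_error(typeQuery(c(q = "ACGT"), fx$sig, refs, "SSU"),
               "absent from signature")
})

test_that("typing a toy signature matches brute force over all 1-column variants", {
  fx <- refFixture()
  refs <- list(ITS = fx$aln)
  base <- "ACGTACGTACGT"
  diagCols <- sort(unique(diagnosticTriples(fx$sig)$column))
  states <- function(cl, col)
    fx$sig@entries[[paste0("state_", cl)]][fx$sig@entries$column == col]
  for (col in 1:12) for (s in c("A", "C", "G", "T")) {
    q <- base
    substr(q, col, col) <- s
    got <- typeQuery(c(q = q), fx$sig, refs, "ITS")
    ## brute force the contract on this fully covered query
    match1 <- all(vapply(diagCols, function(cc)
      substr(q, cc, cc) == states("R1", cc), logical(1)))
    match2 <- all(vapply(diagCols, function(cc)
      substr(q, cc, cc) == states("R2", cc), logical(1)))
    want <- if (match1 && match2) "AMBIGUOUS"
            else if (match1) "ASSIGNED(R1)"
            else if (match2) "ASSIGNED(R2)" else "CONFLICT"
    if (want %in% c("ASSIGNED(R1)", "ASSIGNED(R2)"))
      expect_identical(got$final_call, want)
    else expect_identical(got$call_type, want)
  }
})

test_that("typing reference records recovers their clade; weaker markers only
           broaden the call", {
  sim <- simulateSyngens(referencePreset(seed = 11))
  disc <- discoverSignatures(sim$alignments, sim$meta)
  refs <- disc$refAlns
  truth <- sim$truth$cladeOf

  its <- makeQueries(sim, "ITS", seed = 1)
  callsIts <- batchType(its$queries, disc$signature, refs, "ITS")
  expect_true(all(callsIts$call_type == "ASSIGNED"))
  expect_identical(callsIts$final_call,
                   paste0("ASSIGNED(", unname(truth[its$truth$source_id]), ")"))

  ## the SSU cannot separate R1 from R2: calls broaden, never flip
  ssu <- makeQueries(sim, "SSU", seed = 2)
  callsSsu <- batchType(ssu$queries, disc$signature, refs, "SSU")
  for (i in seq_len(nrow(callsSsu))) {
    cl <- unname(truth[ssu$truth$source_id[i]])
    if (cl %in% c("R1", "R2")) {
      expect_identical(callsSsu$final_call[i], "AMBIGUOUS(R1,R2)")
    } else {
      expect_identical(callsSsu$final_call[i], paste0("ASSIGNED(", cl, ")"))
    }
  }
})

test_that("assignment accuracy is perfect at zero error and non-increasing
           in the per-site error rate", {
  sim <- simulateSyngens(referencePreset(seed = 21))
  disc <- discoverSignatures(sim$alignments, sim$meta)
  acc <- vapply(c(0, 0.005, 0.02), function(e) {
    q <- makeQueries(sim, "ITS", errorRate = e, seed = 31)
    calls <- batchType(q$queries, disc$signature, disc$refAlns, "ITS")
    mean(calls$final_call ==
           paste0("ASSIGNED(", unname(sim$truth$cladeOf[q$truth$source_id]),
                  ")"))
  }, numeric(1))
  expect_identical(acc[1], 1)
  expect_true(all(diff(acc) <= 0))
})

test_that("batches tolerate empty input and per-record failures", {
  fx <- refFixture()
  refs <- list(ITS = fx$aln)
  empty <- batchType(character(), fx$sig, refs, "ITS")
  expect_identical(nrow(empty), 0L)
  mixed <- batchType(c(good = "ACGTACGTACGT", bad = "----"), fx$sig, refs,
                     "ITS")
  expect_identical(mixed$call_type, c("ASSIGNED", "ERROR"))
  expect_match(mixed$error[2], "empty query")
})
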