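test_that("variable-column detection honours the missing-data policy", {
  aln <- toyAlignment(c("ACGT", "ACGT", "ACGT", "ACGT"))
  part <- toyPartition(aln, c("R1", "R1", "R2", "R2"))
  expect_length(findVariableColumns(aln, part), 0L)  # no variation

  aln2 <- toyAlignment(c("ACGT", "ACGA", "ACGT"))
  part2 <- toyPartition(aln2, c("R1", "R1", "R2"))
  prof <- findVariableColumns(aln2, part2)
  expect_identical(prof@columns, 4L)

  ## a gap/N difference is not variation under "ignore" but is under "as_state"
  aln3 <- toyAlignment(c("AC-T", "ACNT", "ACTT"))
  part3 <- toyPartition(aln3, c("R1", "R1", "R2"))
  expect_identical(findVariableColumns(aln3, part3, "ignore")@columns,
                   integer(0))
  expect_identical(findVariableColumns(aln3, part3, "as_state")@columns, 3L)
  ## accounting invariant is enforced by the class validity
  expect_identical(prof@nRecords, 3L)
})

test_that("classification realizes the category definitions", {
  ## both clades fixed for private states -> diagnostic for both
  aln <- toyAlignment(c("AA", "AA", "AC", "AC"))
  part <- toyPartition(aln, c("R1", "R1", "R2", "R2"))
  sig <- classifyColumns(findVariableColumns(aln, part), part)
  expect_identical(sig@entries$category, "SYNAPOMORPHY")
  expect_identical(sig@entries$column, 2L)
  expect_identical(sig@entries$diagnostic_for, "R1,R2")

  ## within-clade variation, no clade diagnostic
  aln2 <- toyAlignment(c("AA", "AC", "AA", "AA"))
  part2 <- toyPartition(aln2, c("R1", "R1", "R2", "R2"))
  sig2 <- classifyColumns(findVariableColumns(aln2, part2), part2)
  expect_identical(sig2@entries$category, "WITHIN_CLADE_VARIABLE")
  expect_identical(sig2@entries$diagnostic_for, "")

  ## a state shared by two clades against a third -> OTHER_VARIABLE for the
  ## pair's column unless the third clade's state is private to it
  aln3 <- toyAlignment(c("AG", "AG", "AG", "AG", "AT", "AT"))
  part3 <- toyPartition(aln3, c("R1", "R1", "R2", "R2", "R3", "R3"))
  sig3 <- classifyColumns(findVariableColumns(aln3, part3), part3)
  expect_identical(sig3@entries$category, "SYNAPOMORPHY")
  expect_identical(sig3@entries$diagnostic_for, "R3")

  ## UNKNOWN records block exclusivity but never found a synapomorphy
  aln4 <- toyAlignment(c("AC", "AC", "AT", "AC"))
  part4 <- toyPartition(aln4, c("R1", "R1", "R2", "UNKNOWN"))
  sig4 <- classifyColumns(findVariableColumns(aln4, part4), part4)
  expect_identical(sig4@entries$diagnostic_for, "R2")  # C carried by UNKNOWN

  onlyR1 <- CladePartition(recordIds(aln4), rep("R1", 4))
  expect_error(classifyColumns(findVariableColumns(aln4, onlyR1), onlyR1),
               "at least 2 labelled clades")
})

test_that("classification agrees with direct enumeration on a random corpus", {
  runDiagnosticsCorpus(nCases = 150, seed = 20240601)
})

test_that("signatures are invariant under record permutation", {
  set.seed(99)
  for (case in seq_len(25)) {
    rc <- randomCase()
    labelled <- setdiff(unique(cladeOf(rc$partition)), "UNKNOWN")
    if (length(labelled) < 2L) next
    sig <- classifyColumns(findVariableColumns(rc$aln, rc$partition),
                           rc$partition)
    perm <- sample(length(rc$aln))
    alnP <- rc$aln[perm]
    partP <- CladePartition(recordIds(alnP),
                            unname(cladeOf(rc$partition)[recordIds(alnP)]))
    sigP <- classifyColumns(findVariableColumns(alnP, partP), partP)
    expect_identical(sig@entries, sigP@entries)
  }
})

test_that("adding a record never creates synapomorphies for other clades", {
  set.seed(7)
  for (case in seq_len(50)) {
    rc <- randomCase(withMissing = FALSE)
    labelled <- setdiff(unique(cladeOf(rc$partition)), "UNKNOWN")
    if (length(labelled) < 2L) next
    diagPairs <- function(aln, part) {
      sig <- classifyColumns(findVariableColumns(aln, part), part)
      dg <- diagnosticTriples(sig)
      paste(dg$column, dg$clade)
    }
    before <- diagPairs(rc$aln, rc$partition)
    target <- sample(labelled, 1L)
    newSeq <- paste(sample(c("A", "C", "G", "T"), alignmentLength(rc$aln),
                           replace = TRUE), collapse = "")
    aln2 <- MarkerAlignment(c(recordIds(rc$aln), "new"),
                            c(unname(sequences(rc$aln)), newSeq), "ITS")
    part2 <- CladePartition(recordIds(aln2),
                            c(unname(cladeOf(rc$partition)), target))
    after <- diagPairs(aln2, part2)
    otherAfter <- after[!grepl(paste0(" ", target, "$"), after)]
    expect_true(all(otherAfter %in% before))
  }
})

test_that("marker combination reports separability alone and combined", {
  ## SSU-like marker: R1 and R2 share every derived state
  ssu <- toyAlignment(c("GG", "GG", "GG", "GG", "GA", "GA"), marker = "SSU")
  its <- toyAlignment(c("CA", "CA", "CT", "CT", "CG", "CG"), marker = "ITS")
  part <- toyPartition(ssu, c("R1", "R1", "R2", "R2", "R3", "R3"))
  sSsu <- classifyColumns(findVariableColumns(ssu, part), part)
  sIts <- classifyColumns(findVariableColumns(its, part), part)
  comb <- combineMarkers(list(sSsu, sIts))
  sep <- separability(comb)
  expect_identical(sep$SSU, c(FALSE, FALSE, TRUE))
  expect_identical(sep$ITS, c(TRUE, TRUE, TRUE))
  expect_identical(sep$combined, c(TRUE, TRUE, TRUE))

  ## idempotence: a fully diagnostic single marker equals its combination
  alone <- combineMarkers(list(sIts))
  expect_identical(separability(alone)$combined, c(TRUE, TRUE, TRUE))
  expect_identical(diagnosticTriples(alone)[, c("column", "clade", "state")],
                   diagnosticTriples(sIts)[, c("column", "clade", "state")])

  ## clades with no diagnostic triple anywhere are flagged non-separable
  flat <- toyAlignment(c("AA", "AC", "AA", "AC", "AG", "AG"), marker = "SSU")
  sFlat <- classifyColumns(findVariableColumns(flat, part), part)
  sepF <- separability(combineMarkers(list(sFlat)))
  expect_identical(sepF$combined, c(FALSE, FALSE, TRUE))

  expect_error(combineMarkers(list(sSsu, classifyColumns(
    findVariableColumns(its, toyPartition(its, c("R1", "R1", "R2", "R2",
                                                 "R4", "R4"))),
    toyPartition(its, c("R1", "R1", "R2", "R2", "R4", "R4"))))),
    "clade sets differ")
})

test_that("signature reports round-trip through TSV", {
  sim <- simulateSyngens(referencePreset(seed = 3))
  disc <- discoverSignatures(sim$alignments, sim$meta)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeSignatureReport(disc$signature, f)
  back <- readSignatureReport(f)
  expect_identical(back@entries, disc$signature@entries)
  expect_identical(back@separability, disc$signature@separability)
  ## stable ordering by (marker, column), 5 state columns in R1..R5 order
  expect_identical(grep("^state_", names(back@entries), value = TRUE),
                   paste0("state_", syngenLevels()))
  expect_false(is.unsorted(back@entries$column[back@entries$marker == "ITS"]))

  ## empty signature -> header-only file
  aln <- toyAlignment(c("AA", "AA", "AA", "AA"))
  part <- toyPartition(aln, c("R1", "R1", "R2", "R2"))
  empty <- classifyColumns(findVariableColumns(aln, part), part)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeSignatureReport(combineMarkers(list(empty)), f2)
  expect_length(readLines(f2), 1L)
})
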