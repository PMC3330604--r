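test_that("identity alignment sums the diagonal scores", {
  aln <- smithWaterman("ACGT", "ACGT", b62)
  expect_equal(alignmentScore(aln), 4 + 9 + 6 + 5)
  expect_equal(matchCount(aln), 4L)
  expect_equal(similarityRatio(aln), 1)
  expect_equal(as.integer(c(IRanges::start(queryRange(aln)),
                            IRanges::end(queryRange(aln)))), c(1L, 4L))
  expect_false(grepl("-", aln@alignedQuery, fixed = TRUE))
})

test_that("self-alignment of random sequences is full-length and gapless", {
  set.seed(42)
  mat <- substitutionMatrix(b62)
  for (i in 1:20) {
    s <- randSeq(sample(5:60, 1))
    aln <- smithWaterman(s, s, b62)
    ch <- strsplit(s, "")[[1]]
    expect_equal(alignmentScore(aln), sum(mat[cbind(ch, ch)]))
    expect_equal(similarityRatio(aln), 1)
    expect_equal(consumedBases(aln), nchar(s))
    expect_false(grepl("-", aln@alignedQuery, fixed = TRUE))
  }
})

test_that("scores agree with the exhaustive gap-enumeration oracle", {
  set.seed(101)
  for (scheme in list(b62, nuc)) {
    for (i in 1:60) {
      q <- randSeq(sample(2:8, 1))
      r <- randSeq(sample(5:20, 1))
      expect_equal(alignmentScore(smithWaterman(q, r, scheme)),
                   oracleScore(q, r, scheme),
                   info = paste(q, r))
    }
  }
})

test_that("scores agree with Biostrings pairwiseAlignment", {
  # Biostrings charges gapOpening + L * gapExtension for a gap of length L;
  # shifting its opening by one extension matches this package's
  # open + (L - 1) * extension convention.
  sub <- substitutionMatrix(b62)[c("A", "C", "G", "T"), c("A", "C", "G", "T")]
  set.seed(7)
  for (i in 1:40) {
    q <- randSeq(sample(6:25, 1))
    r <- randSeq(sample(20:80, 1))
    mine <- alignmentScore(smithWaterman(q, r, b62))
    bs <- Biostrings::pairwiseAlignment(
      q, r, type = "local", substitutionMatrix = sub,
      gapOpening = gapOpening(b62) - gapExtension(b62),
      gapExtension = gapExtension(b62))
    expect_equal(mine, max(0, Biostrings::score(bs)))
  }
})

test_that("appending reference bases never decreases the score", {
  set.seed(11)
  for (i in 1:15) {
    q <- randSeq(sample(4:12, 1))
    r <- randSeq(sample(10:30, 1))
    s1 <- alignmentScore(smithWaterman(q, r, b62))
    s2 <- alignmentScore(smithWaterman(q, paste0(r, randSeq(5)), b62))
    expect_gte(s2, s1)
  }
})

test_that("swapping query and reference preserves the optimal score", {
  set.seed(13)
  for (i in 1:15) {
    a <- randSeq(sample(5:15, 1))
    b <- randSeq(sample(5:40, 1))
    expect_equal(alignmentScore(smithWaterman(a, b, b62)),
                 alignmentScore(smithWaterman(b, a, b62)))
  }
})

test_that("aligned strings are consistent and price their gaps correctly", {
  set.seed(99)
  ref <- randSeq(400)
  for (i in 1:15) {
    # two nearby reference pieces with a small deletion between them force
    # gapped optima
    s <- sample(300, 1)
    gap <- sample(2:6, 1)
    q <- paste0(substr(ref, s, s + 19), substr(ref, s + 20 + gap, s + 45 + gap))
    aln <- smithWaterman(q, ref, b62)
    expect_equal(gsub("-", "", aln@alignedQuery),
                 substr(q, aln@queryStart, aln@queryEnd))
    expect_equal(gsub("-", "", aln@alignedRef),
                 substr(ref, aln@refStart, aln@refEnd))
    qg <- strsplit(aln@alignedQuery, "")[[1]] == "-"
    rg <- strsplit(aln@alignedRef, "")[[1]] == "-"
    expect_false(any(qg & rg))
    expect_equal(scoreFromStrings(aln@alignedQuery, aln@alignedRef, b62),
                 alignmentScore(aln))
  }
})

test_that("N is scored as neutral and never breaks an alignment", {
  expect_equal(alignmentScore(smithWaterman("ACNGT", "ACTGT", b62)),
               4 + 9 + 0 + 6 + 5)
  # trailing neutral column is not included (smaller end cell preferred)
  aln <- smithWaterman("ACGTN", "ACGTN", b62)
  expect_equal(alignmentScore(aln), 24)
  expect_equal(matchCount(aln), 4L)
})

test_that("unscoreable residues are reported with their position", {
  expect_error(smithWaterman("ACZT", "ACGT", nuc),
               "residue 'Z' at position 3")
  expect_error(smithWaterman("ACGT", "AC-T", nuc), "position 3")
})

test_that("an alignment with nothing above zero is empty", {
  aln <- smithWaterman("AAAA", "CCCC", nuc)
  expect_equal(alignmentScore(aln), 0)
  expect_equal(matchCount(aln), 0L)
  expect_equal(similarityRatio(aln), 0)
  expect_equal(consumedBases(aln), 0L)
})

test_that("similarity ratio uses the full query length as denominator", {
  aln <- smithWaterman("ACGT", "ACGT", b62)
  expect_equal(similarityRatio(aln, queryLength = 40), 0.1)
  expect_error(similarityRatio(aln, queryLength = 3), "inconsistent")
  expect_error(similarityRatio(aln, queryLength = 0), "positive")
})
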