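test_that("deletion calling follows the interval arithmetic", {
  del <- callDeletion(1427, 2071)
  expect_equal(del$length, 643L)
  expect_equal(c(del$start, del$end), c(1428L, 2070L))

  tiny <- callDeletion(10, 12)
  expect_equal(tiny$length, 1L)
  expect_equal(c(tiny$start, tiny$end), c(11L, 11L))

  expect_error(callDeletion(10, 11), "no deletion between parts")
  expect_error(callDeletion(10, 10), "no deletion between parts")
  expect_error(callDeletion(10, 3), "no deletion between parts")
})

test_that("EDPE is the absolute boundary difference in bases", {
  expect_equal(edpe(37, 27), 10L)
  expect_equal(edpe(27, 27), 0L)
  expect_equal(edpe(5, 9), 4L)
  expect_error(edpe(NA, 3), "NA")
})

test_that("binary-search step size halves each iteration", {
  expect_equal(stepSize(40, 1), 10L)
  expect_equal(stepSize(40, 2), 5L)
  expect_equal(stepSize(40, 3), 2L)
  expect_equal(stepSize(40, 4), 1L)
  expect_equal(stepSize(40, 5), 0L)  # schedule exhausted
  expect_equal(stepSize(1000, 1), 250L)
  expect_error(stepSize(40, 0), "iteration")
  expect_error(stepSize(0, 1), "queryLength")
})

test_that("classical boundary is the consumed-base count", {
  set.seed(5)
  ref <- syntheticReference(400)
  q <- substr(ref, 101, 140)
  expect_equal(classicalSWBoundary(q, ref, b62), 40L)

  fx <- unambiguousDeletionFixture(500, 30, 25, 100, seed = 3)
  est <- classicalSWBoundary(fx$query, fx$reference, b62)
  expect_gte(est, 30L)  # at least the former fragment is consumed
})

test_that("prefix-fused incremental scan equals standalone alignments", {
  set.seed(21)
  sch <- b62
  lk <- PartialAlign:::.schemeLookup(sch)
  for (rep in 1:3) {
    q <- randSeq(15)
    r <- randSeq(100)
    qc <- PartialAlign:::.encodeSeq(q, lk)
    rc <- PartialAlign:::.encodeSeq(r, lk)
    scan <- PartialAlign:::.prefixScan(qc, rc, lk, sch)
    for (L in 1:15) {
      aln <- smithWaterman(substr(q, 1, L), r, sch)
      expect_equal(scan[L, 1], alignmentScore(aln))
      expect_equal(as.integer(scan[L, 2]), matchCount(aln))
      if (alignmentScore(aln) > 0) {
        expect_equal(as.integer(scan[L, 3:6]),
                     c(aln@queryStart, aln@queryEnd,
                       aln@refStart, aln@refEnd))
      }
    }
  }
})

test_that("incremental search finds the boundary and the deleted interval", {
  fx <- unambiguousDeletionFixture(500, 27, 13, 100, seed = 1,
                                   threshold = c(0.9, 0.97))
  tr <- fx$truth

  # at threshold 1.0 the scan stops immediately past the true boundary
  res <- incrementalPartialAlign(fx$query, fx$reference, 1.0, 20, b62)
  expect_equal(boundaryEstimate(res), tr$true_boundary)
  expect_equal(res@status, "deletion")
  expect_equal(res@deletionLength, tr$true_deletion_length)
  expect_equal(res@former@refStart, tr$former_ref_start)
  expect_equal(res@former@refEnd, tr$former_ref_end)
  expect_equal(res@latter@refStart, tr$latter_ref_start)
  expect_equal(res@latter@refEnd, tr$latter_ref_end)

  # at lower thresholds the boundary overshoots deterministically: the
  # prefix ratio t/L stays at or above the threshold until L exceeds
  # t/threshold, so the boundary lands on floor(t/threshold).  The former
  # mapping still ends at the fragment end, but the latter part now starts
  # inside the latter fragment, so the called deletion grows by exactly
  # the overshoot.
  res9 <- incrementalPartialAlign(fx$query, fx$reference, 0.9, 20, b62)
  expect_equal(boundaryEstimate(res9), 30L)  # floor(27 / 0.9)
  expect_equal(edpe(boundaryEstimate(res9), tr$true_boundary), 3L)
  expect_equal(res9@former@refEnd, tr$former_ref_end)
  expect_equal(res9@deletionLength, tr$true_deletion_length + 3L)

  # call accounting: 1 full alignment + prefixes from minLength through
  # the stopping length + 1 latter-part alignment
  expect_equal(swCalls(res9), 1L + (31L - 20L + 1L) + 1L)
})

test_that("incremental search reports no deletion for substrings", {
  set.seed(8)
  ref <- syntheticReference(400)
  q <- substr(ref, 51, 130)
  res <- incrementalPartialAlign(q, ref, 0.9, 20, b62)
  expect_equal(res@status, "no_deletion")
  expect_true(is.na(boundaryEstimate(res)))
  expect_null(res@former)
  expect_equal(swCalls(res), 1L)
  expect_equal(estimatedBoundary(res), 80L)  # falls back to consumed bases
})

test_that("partial-align argument errors are informative", {
  set.seed(8)
  ref <- syntheticReference(200)
  expect_error(incrementalPartialAlign("ACGTACGTA", ref, 0.9, 20, b62),
               "shorter than 2 \\* minLength")
  expect_error(binaryPartialAlign("ACGTACGTA", ref, 0.9, 20, b62),
               "shorter than 2 \\* minLength")
  expect_error(binaryPartialAlign(substr(ref, 1, 60), ref, 1.5, 20, b62),
               "threshold")
  expect_error(binaryPartialAlign(substr(ref, 1, 60), ref, 0.9, 0, b62),
               "minLength")
})

test_that("binary search follows the halving schedule to the boundary", {
  fx <- unambiguousDeletionFixture(500, 27, 13, 100, seed = 2)
  res <- binaryPartialAlign(fx$query, fx$reference, 0.9, 20, b62)
  tr <- alignmentTrace(res)
  expect_equal(tr$former_length, c(20L, 30L, 25L, 27L))
  expect_equal(tr$latter_length, c(20L, 10L, 15L, 13L))
  expect_equal(tr$former_length + tr$latter_length,
               rep(nchar(fx$query), 4))
  expect_equal(tr$step[1:3], c(10L, 5L, 2L))
  # each move is exactly the recorded step
  expect_equal(abs(diff(tr$former_length)), tr$step[1:3])
  expect_equal(boundaryEstimate(res), 27L)
  expect_true(res@converged)
  expect_equal(res@status, "deletion")
  expect_equal(res@deletionLength, fx$truth$true_deletion_length)
  expect_equal(swCalls(res), 1L + 2L * nrow(tr))
})

test_that("binary search reports no deletion for substrings", {
  set.seed(9)
  ref <- syntheticReference(400)
  res <- binaryPartialAlign(substr(ref, 11, 90), ref, 0.9, 20, b62)
  expect_equal(res@status, "no_deletion")
  expect_true(is.na(boundaryEstimate(res)))
})

test_that("a latter part mapping upstream is flagged discordant", {
  set.seed(17)
  ref <- syntheticReference(600)
  # fragments concatenated in reverse reference order: no deletion exists
  q <- paste0(substr(ref, 301, 330), substr(ref, 21, 60))
  for (res in list(incrementalPartialAlign(q, ref, 0.9, 20, b62),
                   binaryPartialAlign(q, ref, 0.9, 20, b62))) {
    expect_equal(res@status, "discordant")
    expect_true(is.na(res@deletionLength))
  }
})

test_that("called deletions satisfy the interval bookkeeping", {
  # deletion_length + former span + latter span == total reference span
  set.seed(33)
  for (i in 1:10) {
    fx <- unambiguousDeletionFixture(800, sample(20:60, 1), sample(20:60, 1),
                                     150, threshold = 0.9)
    for (res in list(
      incrementalPartialAlign(fx$query, fx$reference, 0.9, 20, b62),
      binaryPartialAlign(fx$query, fx$reference, 0.9, 20, b62))) {
      if (res@status != "deletion") next
      a <- res@former@refStart; b <- res@former@refEnd
      cc <- res@latter@refStart; d <- res@latter@refEnd
      expect_equal(res@deletionLength + (b - a + 1L) + (d - cc + 1L),
                   d - a + 1L)
      expect_equal(res@deletionLength, cc - b - 1L)
    }
  }
})

test_that("call counts respect the complexity bounds", {
  set.seed(55)
  ref <- syntheticReference(4000)
  for (i in 1:6) {
    sim <- makeQuery(ref, c(100L, 300L), minFragment = 20L,
                     minDeletion = 1000L)
    l <- nchar(sim$query)
    bin <- binaryPartialAlign(sim$query, ref, 0.9, 20, b62)
    inc <- incrementalPartialAlign(sim$query, ref, 0.9, 20, b62)
    expect_lte(swCalls(bin), 1L + 2L * (ceiling(log2(l)) + 1L))
    expect_lte(swCalls(inc), l - 20L + 2L)
  }
})
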