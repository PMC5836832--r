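test_that("sequence encoding maps ACGT case-insensitively and rejects others", {
  expect_identical(encodeSequence("ACGT"), c(0L, 1L, 2L, 3L))
  expect_identical(encodeSequence("acgt"), c(0L, 1L, 2L, 3L))
  expect_error(encodeSequence("ACNT"), "position 3")
  expect_error(encodeSequence(""), "non-empty")
  expect_error(encodeSequence(c("AC", "GT")), "single")
})

test_that("scheme invariants are enforced", {
  expect_error(scoringScheme(gapExtend = 0), "strictly positive")
  expect_error(scoringScheme(gapOpen = -1), "non-negative")
  # min s must exceed -(GoH+GeH+GoV+GeV)
  expect_error(scoringScheme(match = 1, mismatch = -4, gapOpen = 1,
                             gapExtend = 1), "must exceed")
  expect_error(scoringScheme(match = -1, mismatch = -1, gapOpen = 2,
                             gapExtend = 1), "non-negative")
  sc <- scoringScheme(match = 2, mismatch = -2, gapOpen = 4, gapExtend = 1)
  expect_equal(maxSub(sc), 2)
})

test_that("reference fill handles the trivial and degenerate cases", {
  sc <- scoringScheme()
  dp <- fillReference("ACGT", "ACGT", sc)
  expect_equal(dp@maxScore, 4)
  expect_equal(dp@maxCell, c(4L, 4L))
  expect_error(fillReference("A", "", sc), "non-empty")
  # edge initialization
  expect_equal(dp@S[1, ], c(0, -2, -3, -4, -5))
  expect_equal(dp@S[, 1], c(0, -2, -3, -4, -5))
})

test_that("reference fill matches the exhaustive alignment enumerator", {
  # the repeat-expansion pair under a 2/-2/4/1 scheme
  sc <- scoringScheme(match = 2, mismatch = -2, gapOpen = 4, gapExtend = 1)
  a <- encodeSequence("ACACACAC"); b <- encodeSequence("ACACAC")
  bf <- bruteForceBest(a, b, sc)
  dp <- fillReference(a, b, sc)
  expect_equal(dp@maxScore, bf$score)
  expect_equal(dp@maxCell, bf$cell)
  expect_equal(dp@S, bruteForceMatrix(a, b, sc), ignore_attr = TRUE)
  # random small instances, random schemes
  set.seed(11)
  for (k in 1:6) {
    a <- rSeq(sample(2:7, 1)); b <- rSeq(sample(2:5, 1))
    sc <- rScheme()
    dp <- fillReference(a, b, sc)
    expect_equal(dp@S, bruteForceMatrix(a, b, sc), ignore_attr = TRUE)
    bf <- bruteForceBest(a, b, sc)
    expect_equal(dp@maxScore, bf$score)
    expect_equal(dp@maxCell, bf$cell)
  }
})

test_that("traceback emits the documented encoding and replays to the score", {
  sc <- scoringScheme()
  dp <- fillReference("ACGT", "ACGT", sc)
  expect_equal(pathChars(tracebackReference(dp)), "10101010")
  # forced gap-only tail: trace from the far corner of AAAA vs AA
  dp2 <- fillReference("AAAA", "AA", sc)
  p2 <- tracebackReference(dp2, start = c(4L, 2L))
  expect_equal(sum(pathBits(p2) == 0L), 4L)       # zeros consume a
  expect_equal(length(decodePath(p2)[decodePath(p2) == "H"]), 2L)
  expect_equal(length(pathBits(p2)), 4L + 2L)
  # replay property over random instances
  set.seed(5)
  for (k in 1:10) {
    a <- rSeq(30); b <- rSeq(30); sc <- rScheme()
    dp <- fillReference(a, b, sc)
    pth <- tracebackReference(dp)
    rp <- replayPath(pth, a, b, sc)
    expect_equal(rp$score, dp@maxScore)
    expect_equal(c(rp$aConsumed, rp$bConsumed), as.integer(dp@maxCell))
  }
})

test_that("swapping sequences and gap orientations transposes S", {
  set.seed(9)
  a <- rSeq(12); b <- rSeq(17)
  sc <- scoringScheme(match = 2, mismatch = -1, gapOpenH = 3, gapExtendH = 1,
                      gapOpenV = 1, gapExtendV = 2)
  scT <- scoringScheme(match = 2, mismatch = -1, gapOpenH = 1, gapExtendH = 2,
                       gapOpenV = 3, gapExtendV = 1)
  expect_equal(fillReference(a, b, sc)@S, t(fillReference(b, a, scT)@S))
})

test_that("unit edit-cost scheme reproduces the Levenshtein distance", {
  sc <- scoringScheme(match = 0, mismatch = -1, gapOpen = 0, gapExtend = 1)
  set.seed(21)
  for (k in 1:8) {
    a <- rSeq(sample(3:25, 1)); b <- rSeq(sample(3:25, 1))
    dp <- fillReference(a, b, sc)
    ed <- adist(paste(c("A", "C", "G", "T")[a + 1], collapse = ""),
                paste(c("A", "C", "G", "T")[b + 1], collapse = ""))[1, 1]
    expect_equal(-dp@S[length(a) + 1, length(b) + 1], ed)
  }
})
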