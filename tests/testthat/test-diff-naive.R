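test_that("difference edges carry the clipped initial conditions", {
  sc <- scoringScheme(match = 2, mismatch = -1, gapOpenH = 3, gapExtendH = 1,
                      gapOpenV = 2, gapExtendV = 2)
  st <- fillDiffNaive("ACGTAC", "GGTAC", sc)
  expect_true(all(st@dE[1, -1] == -sc@GoH))     # i = 0 column
  expect_true(all(st@dF[-1, 1] == -sc@GoV))     # j = 0 row
  expect_true(all(st@dE[, 1] == 0))
  expect_true(all(st@dF[1, ] == 0))
  expect_equal(st@dH[-1, 1], c(-(sc@GoH + sc@GeH), rep(-sc@GeH, 5)))
  expect_equal(st@dV[1, -1], c(-(sc@GoV + sc@GeV), rep(-sc@GeV, 4)))
})

test_that("reconstruction reproduces the nondifference matrices exactly", {
  set.seed(31)
  for (k in 1:10) {
    a <- rSeq(40); b <- rSeq(40); sc <- rScheme()
    dp <- fillReference(a, b, sc)
    rec <- reconstructAbsolute(fillDiffNaive(a, b, sc))
    expect_identical(rec@S, dp@S)
    expect_identical(rec@E[-1, -1], dp@E[-1, -1])   # interior
    expect_identical(rec@F[-1, -1], dp@F[-1, -1])
    expect_identical(rec@maxScore, dp@maxScore)
    expect_identical(rec@maxCell, dp@maxCell)
    expect_identical(pathChars(tracebackReference(rec)),
                     pathChars(tracebackReference(dp)))
  }
})

test_that("reconstruction telescopes correctly in degenerate cases", {
  sc <- scoringScheme(gapOpenV = 3, gapExtendV = 2)
  # all-zero differences telescope to S == 0
  z <- matrix(0, 5, 5)
  st0 <- methods::new("NaiveDiffState", a = rep(0L, 4), b = rep(0L, 4),
                      scheme = sc, dH = z, dV = z, dE = z, dF = z, A = z)
  expect_true(all(reconstructAbsolute(st0)@S == 0))
  # the i = 0 column alone gives the gap-penalty edge
  st <- fillDiffNaive("ACG", "TTAGC", sc)
  S <- reconstructAbsolute(st)@S
  expect_equal(S[1, ], c(0, -sc@GoV - (1:5) * sc@GeV))
})

test_that("order-dependent reconstruction is reported as corruption", {
  st <- fillDiffNaive("ACGTT", "AGCT", scoringScheme())
  st@dH[3, 3] <- st@dH[3, 3] + 1
  expect_error(reconstructAbsolute(st), "path-independence")
})

test_that("bounding formulae hold on every fill and catch violations", {
  set.seed(41)
  for (k in 1:15) {
    a <- rSeq(sample(1:30, 1)); b <- rSeq(sample(1:30, 1)); sc <- rScheme()
    st <- fillDiffNaive(a, b, sc)
    chk <- checkNaiveBounds(st)
    expect_true(chk$pass)
    # path independence on interior cells
    la <- length(a); lb <- length(b)
    if (la >= 1 && lb >= 1) {
      ii <- 2:(la + 1); jj <- 2:(lb + 1)
      lhs <- st@dH[ii, jj, drop = FALSE] + st@dV[ii - 1, jj, drop = FALSE]
      rhs <- st@dV[ii, jj, drop = FALSE] + st@dH[ii, jj - 1, drop = FALSE]
      expect_equal(lhs, rhs)
      expect_equal(lhs, st@A[ii, jj, drop = FALSE])
    }
  }
  # injected violation names the offending matrix
  st <- fillDiffNaive("ACGT", "ACT", scoringScheme())
  st@dH[2, 2] <- maxSub(st@scheme) + st@scheme@GoV + st@scheme@GeV + 1
  chk <- checkNaiveBounds(st)
  expect_false(chk$pass)
  expect_false(chk$report$pass[chk$report$matrix == "dH"])
})

test_that("the no-error guarantee of the clipped edges holds", {
  # E[0,j] clipped to S[0,j] - GoH satisfies
  # E[0,j] - GeH <= S[0,j] - GoH - GeH (with equality), and under the
  # sampled schemes the clipped branch never changes the first interior row
  set.seed(43)
  for (k in 1:5) {
    a <- rSeq(6); b <- rSeq(6); sc <- rScheme()
    rec <- reconstructAbsolute(fillDiffNaive(a, b, sc))
    expect_true(all(rec@E[1, -1] - sc@GeH <= rec@S[1, -1] - sc@GoH - sc@GeH))
    expect_true(all(rec@F[-1, 1] - sc@GeV <= rec@S[-1, 1] - sc@GoV - sc@GeV))
    expect_identical(rec@S[2, ], fillReference(a, b, sc)@S[2, ])
  }
})

test_that("narrow-width claims follow from the bound endpoints", {
  # M = 2, Go = 4, Ge = 1: 4 signed bits suffice, and no fill escapes them
  sc <- scoringScheme(match = 2, mismatch = -2, gapOpen = 4, gapExtend = 1)
  expect_equal(minSignedBits(sc), 4L)
  set.seed(51)
  for (k in 1:20) {
    st <- fillDiffNaive(rSeq(50), rSeq(50), sc)
    vals <- c(st@dH, st@dV, st@dE, st@dF)
    expect_true(all(vals >= -8 & vals <= 7, na.rm = TRUE))
  }
  # unit scheme: dE stays within [-GoH, 0]
  stu <- fillDiffNaive(rSeq(40), rSeq(40), scoringScheme())
  expect_true(all(stu@dE >= -1 & stu@dE <= 0, na.rm = TRUE))
  # tiny scheme: endpoints are +-1, two bits
  expect_equal(minSignedBits(scoringScheme(match = 0, mismatch = -1,
                                           gapOpen = 0, gapExtend = 1)), 2L)
  # benchmark unit scheme: smallest w with endpoints in two's-complement range
  sc1 <- scoringScheme()
  ep <- c(-2, 3, -2, 3, -1, 0, -1, 0)
  w <- 1L
  while (!(min(ep) >= -2^(w - 1) && max(ep) <= 2^(w - 1) - 1)) w <- w + 1L
  expect_equal(minSignedBits(sc1), w)
  expect_equal(w, 3L)
})
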