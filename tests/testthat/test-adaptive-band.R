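test_that("band configuration invariants are enforced", {
  expect_error(bandConfig(W = 7), "even")
  expect_error(bandConfig(X = 0), "positive")
  cfg <- bandConfig()
  expect_identical(cfg@W, 32L)
  expect_identical(cfg@blockLen, 32L)
  expect_equal(cfg@W * cfg@blockLen, 1024L)   # cells per block at W = 32
})

test_that("phantom initial conditions follow the printed formulas", {
  sc <- scoringScheme()
  cfg <- bandConfig()
  ph <- phantomInit(sc, cfg)
  expect_identical(ph$L, 0)
  W <- 32L
  expect_equal(ph$d[W / 2 + 1], 0)            # centre lane
  expect_equal(ph$D[W / 2 + 1], -sc@GoH)
  # direct evaluation at q = 0, W = 32, unit scheme: 128/W = 4 exactly
  expect_equal(ph$D[1], -1 + 16 * -(1 + 1 + 1 - 4))
  expect_equal(ph$d[1], 16 * -4)
  # inclined offsets are symmetric about the centre lane
  expect_equal(ph$D[2:W], rev(ph$D[2:W]))
})

test_that("direction choice follows the edge comparison, ties and clamps", {
  # move toward the higher-scoring edge: top lane higher -> right
  expect_identical(chooseDirection(10, 3), "right")
  expect_identical(chooseDirection(3, 10), "down")
  # tie alternates with the previous direction
  expect_identical(chooseDirection(5, 5, prevDirection = "right"), "down")
  expect_identical(chooseDirection(5, 5, prevDirection = "down"), "right")
  # boundary clamps override the comparison
  expect_identical(chooseDirection(10, 3, forceDown = TRUE), "down")
  expect_identical(chooseDirection(3, 10, forceRight = TRUE), "right")
  expect_identical(
    chooseDirection(5, 5, prevDirection = "right",
                    forceRight = TRUE, forceDown = TRUE), "down")
})

test_that("X-drop termination uses a strict threshold", {
  cfg <- bandConfig(X = 50)
  expect_true(xdropTerminate(100 - 51, 100, cfg))
  expect_false(xdropTerminate(100 - 50, 100, cfg))
})

test_that("a band covering the matrix reproduces the reference exactly", {
  set.seed(141)
  for (k in 1:20) {
    la <- sample(1:60, 1); lb <- sample(1:60, 1)
    a <- rSeq(la); b <- rSeq(lb); sc <- rScheme()
    res <- bandFill(a, b, sc, coveringConfig(la, lb))
    dp <- fillReference(a, b, sc)
    expect_identical(res@maxScore, dp@maxScore)
    expect_identical(res@maxCell, dp@maxCell)
    expect_identical(pathChars(tracebackBanded(res)),
                     pathChars(tracebackReference(dp)))
  }
})

test_that("identical sequences walk the diagonal as an alternating zigzag", {
  a <- rep(0:3, 75)   # 300 bp
  res <- bandFill(a, a, scoringScheme(), bandConfig())
  expect_equal(res@maxScore, 300)
  expect_identical(res@maxCell, c(300L, 300L))
  expect_identical(res@terminated, "end")
  dirs <- res@directions[50:length(res@directions)]
  expect_true(all(diff(dirs) != 0))           # strict right/down alternation
})

test_that("blocks are sealed every 32 vectors and offsets rebase exactly", {
  pr <- mutationProfile(length = 600L, seed = 3L)
  g <- generatePair(pr)
  res <- bandFill(g$a, g$b, scoringScheme(), bandConfig())
  ends <- vapply(res@blocks, function(bl) bl$pEnd, integer(1))
  expect_true(all(utils::head(diff(ends), -1) == 32L))
  expect_equal(ends[1], 31L)
  ks <- vapply(res@blocks, function(bl) bl$k, integer(1))
  expect_identical(ks, seq_along(ks) - 1L)
  # rebasing leaves scores and the maximum cell invariant
  res0 <- bandFill(g$a, g$b, scoringScheme(), bandConfig(), rebase = FALSE)
  expect_identical(res@maxScore, res0@maxScore)
  expect_identical(res@maxCell, res0@maxCell)
  expect_true(all(vapply(res0@blocks, function(bl) bl$L, numeric(1)) == 0))
  mx <- findMaxCell(res); mx0 <- findMaxCell(res0)
  expect_identical(mx[c("score", "i", "j", "p")], mx0[c("score", "i", "j", "p")])
  # seal offset of a flat vector with symmetric D is D[W/4]
  W <- 32L
  st <- list(d = rep(0, W), inMat = rep(TRUE, W))
  cs <- list(W = W, D = phantomInit(scoringScheme(), bandConfig())$D)
  expect_equal(diffalign:::.sealDelta(st, cs), cs$D[W / 4 + 1])
})

test_that("block decomposition reconstructs true scores across seals", {
  pr <- mutationProfile(length = 260L, seed = 9L)
  g <- generatePair(pr)
  a <- encodeSequence(g$a); b <- encodeSequence(g$b)
  cfg <- coveringConfig(length(a), length(b))
  res <- bandFill(a, b, scoringScheme(), cfg, keepFlags = FALSE)
  expect_gte(length(res@blocks), 10L)
  S <- fillReference(a, b, scoringScheme())@S
  for (bl in res@blocks) {
    q <- which(bl$inMat) - 1L
    i <- bl$triEnd - q
    j <- bl$pEnd - i
    recon <- bl$L + res@D[q + 1L] + bl$lastD[q + 1L]
    expect_equal(recon, S[cbind(i + 1L, j + 1L)])
  }
})

test_that("flags recomputed from a refilled block equal the originals", {
  pr <- mutationProfile(length = 200L, seed = 5L)
  g <- generatePair(pr)
  sc <- scoringScheme()
  cfg <- bandConfig()
  res <- bandFill(g$a, g$b, sc, cfg)
  cs <- diffalign:::.bandConsts(res@a, res@b, sc, cfg)
  bl <- res@blocks[[2]]
  st <- bl$start
  for (s in seq_along(bl$dirs)) {
    out <- diffalign:::.bandStep(st, bl$dirs[s], cs)
    st <- out$state
    p <- st$p
    expect_identical(out$fH, res@flags$mH[, p + 1L])
    expect_identical(out$fV, res@flags$mV[, p + 1L])
    expect_identical(out$fE, res@flags$mE[, p + 1L])
    expect_identical(out$fF, res@flags$mF[, p + 1L])
  }
  expect_identical(st$d, bl$lastD)
})

test_that("flags mark a planted deletion and stay clear on pure matches", {
  sc <- scoringScheme(match = 2)
  set.seed(161)
  aCode <- rSeq(20)
  bCode <- aCode[-(9:11)]                 # 3-base deletion
  res <- bandFill(aCode, bCode, sc, coveringConfig(20L, 17L))
  cg <- pathToCigar(tracebackBanded(res))
  expect_identical(sum(cg@lengths[cg@ops == "D"]), 3L)
  expect_identical(unname(cigarConsumed(cg)), c(20L, 17L))
  expect_equal(res@maxScore, 17 * 2 - (1 + 3))
  # pure matches: the traced path takes no gap transition at all
  res2 <- bandFill(aCode, aCode, sc, coveringConfig(20L, 20L))
  expect_identical(cigarString(pathToCigar(tracebackBanded(res2))), "20M")
})

test_that("the advance reads only the immediately preceding forefront", {
  # structural: one state argument, and its shape carries a single vector
  # per difference matrix (no second-previous vector anywhere)
  expect_identical(names(formals(diffalign:::.bandStep)),
                   c("st", "dir", "cs"))
  sc <- scoringScheme()
  cfg <- bandConfig()
  cs <- diffalign:::.bandConsts(encodeSequence("ACGT"),
                                encodeSequence("ACGT"), sc, cfg)
  st <- diffalign:::.phantomState(sc, cfg, cs)
  expect_setequal(names(st), c("p", "tri", "HG", "VG", "EG", "FG", "d",
                               "inMat", "L"))
})

test_that("X-drop stops a collapsing alignment but not a high-identity one", {
  set.seed(151)
  good <- generatePair(mutationProfile(length = 1200L, seed = 77L))
  res <- bandFill(good$a, good$b, scoringScheme(), bandConfig())
  expect_identical(res@terminated, "end")
  expect_equal(res@maxCell[1], nchar(good$a), tolerance = 0.02)
  # b shares only its first 300 bases with a: the tail is noise whose
  # best alignment score decays, so the X-drop cuts the fill short of the
  # far corner (random DNA still part-aligns, so the decay is gradual)
  a <- rSeq(900)
  b <- c(a[1:300], rSeq(600))
  res2 <- bandFill(a, b, scoringScheme(), bandConfig())
  expect_identical(res2@terminated, "xdrop")
  expect_lt(res2@nSteps, length(a) + length(b))
  expect_equal(res2@maxScore, 300, tolerance = 0.1)
})

test_that("small-delta width emulation saturates losers and flags overflow", {
  g <- generatePair(mutationProfile(length = 800L, seed = 13L))
  res <- bandFill(g$a, g$b, scoringScheme(),
                  bandConfig(deltaBits = 8))
  expect_identical(res@terminated, "end")
  expect_lte(res@deltaRange[2], 127)
  # a large-M substitution matrix overflows the nominal 8-bit range
  big <- scoringScheme(match = 100, mismatch = -1)
  a <- rep(0L, 300)
  expect_error(bandFill(a, a, big, bandConfig(deltaBits = 8)),
               "small-delta overflow")
})
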