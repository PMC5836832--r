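# Shared fixtures and independent oracles for the test suite.

rSeq <- function(n) sample(0:3, n, replace = TRUE)

# Random scheme satisfying the scheme invariants and the strict edge-clip
# condition min s > -(GeH + GeV), under which the clipped dE/dF edges of
# the difference form reproduce the -inf edges of the nondifference form
# exactly, including traceback paths (see the methods vignette).
rScheme <- function() {
  GeH <- sample(1:2, 1); GeV <- sample(1:2, 1)
  GoH <- sample(0:4, 1); GoV <- sample(0:4, 1)
  mlo <- -(GeH + GeV) + 1L
  v <- seq(max(mlo, -4L), -1L)
  scoringScheme(match = sample(1:3, 1), mismatch = v[sample.int(length(v), 1)],
                gapOpenH = GoH, gapExtendH = GeH,
                gapOpenV = GoV, gapExtendV = GeV)
}

# Exhaustive semi-global alignment enumerator: depth-first search over all
# monotone move sequences from the origin, scoring affine gap runs directly
# on the move string (open + per-move extension, runs broken by any other
# move).  Mirrors the DP's two edge conventions: no vertical move off the
# j = 0 row once a > 0 bases are consumed, no horizontal move off the
# i = 0 column.  Records the best score per end cell; independent of any
# recurrence.
bruteForceMatrix <- function(a, b, scheme) {
  la <- length(a); lb <- length(b)
  tab <- subTable(scheme)
  GoH <- scheme@GoH; GeH <- scheme@GeH
  GoV <- scheme@GoV; GeV <- scheme@GeV
  best <- matrix(-Inf, la + 1L, lb + 1L)
  best[1L, 1L] <- 0
  rec <- function(i, j, score, prev) {
    if (score > best[i + 1L, j + 1L]) best[i + 1L, j + 1L] <<- score
    if (i < la && j < lb)
      rec(i + 1L, j + 1L, score + tab[4L * a[i + 1L] + b[j + 1L] + 1L], "D")
    if (i < la && !(i == 0L && j > 0L))
      rec(i + 1L, j,
          score - (if (prev == "H") 0 else GoH) - GeH, "H")
    if (j < lb && !(j == 0L && i > 0L))
      rec(i, j + 1L,
          score - (if (prev == "V") 0 else GoV) - GeV, "V")
    invisible()
  }
  rec(0L, 0L, 0, "S")
  best
}

bruteForceBest <- function(a, b, scheme) {
  m <- bruteForceMatrix(a, b, scheme)
  mx <- max(m)
  cand <- which(m == mx)
  i <- (cand - 1L) %% nrow(m)
  j <- (cand - 1L) %/% nrow(m)
  o <- order(i + j, i)[1L]
  list(score = mx, cell = c(i[o], j[o]))
}

# All optimal move strings (alignment order, tokens V/H/D) ending at a
# given cell with a given score; used to check the traceback priority.
bruteForceOptimalPaths <- function(a, b, scheme, cell, target) {
  la <- length(a); lb <- length(b)
  tab <- subTable(scheme)
  GoH <- scheme@GoH; GeH <- scheme@GeH
  GoV <- scheme@GoV; GeV <- scheme@GeV
  out <- list()
  rec <- function(i, j, score, prev, moves) {
    if (i == cell[1L] && j == cell[2L] && score == target)
      out[[length(out) + 1L]] <<- moves
    if (i < la && j < lb)
      rec(i + 1L, j + 1L, score + tab[4L * a[i + 1L] + b[j + 1L] + 1L],
          "D", c(moves, "D"))
    if (i < la && !(i == 0L && j > 0L))
      rec(i + 1L, j, score - (if (prev == "H") 0 else GoH) - GeH,
          "H", c(moves, "H"))
    if (j < lb && !(j == 0L && i > 0L))
      rec(i, j + 1L, score - (if (prev == "V") 0 else GoV) - GeV,
          "V", c(moves, "V"))
    invisible()
  }
  rec(0L, 0L, 0, "S", character())
  out
}

# Random valid encodable transition sequence: no H directly after V
# (the structural property of priority-produced paths).
rTokens <- function(n) {
  tok <- character(n)
  prev <- ""
  for (k in seq_len(n)) {
    choices <- if (prev == "V") c("V", "D") else c("V", "H", "D")
    tok[k] <- choices[sample.int(length(choices), 1L)]
    prev <- tok[k]
  }
  tok
}

tokensToPath <- function(tok) {
  bits <- unlist(lapply(tok, function(t)
    switch(t, V = 1L, H = 0L, D = c(1L, 0L))))
  pathString(paste(bits, collapse = ""))
}

# Banded configuration wide enough that the band provably covers every
# antidiagonal of the matrix (all in-matrix cells computed exactly).
coveringConfig <- function(la, lb, X = 1e9) {
  bandConfig(W = 2L * (max(la, lb) + 1L), X = X)
}
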