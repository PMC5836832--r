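#' @include AllClasses.R diffOffset.R
NULL

.RIGHT <- 1L
.DOWN <- 2L

#' Construct an adaptive band configuration
#'
#' @param W integer(1) band width in lanes (even, >= 2); 32 matches the
#'   8-bit SIMD width the data structure is modelled on.
#' @param X numeric(1) X-drop termination threshold in score units.
#' @param deltaBits optional nominal signed bit width for the small-delta
#'   emulation (see [BandConfig-class]); NA disables it.
#' @return a validated [BandConfig-class].
#' @export
bandConfig <- function(W = 32L, X = 50, deltaBits = NA_real_) {
  methods::new("BandConfig", W = as.integer(W), X = as.numeric(X),
               blockLen = 32L, deltaBits = as.numeric(deltaBits))
}

#' Phantom-block initial conditions
#'
#' The banded engine decomposes the absolute score of the cell in lane q of
#' antidiagonal p as L[k] + D[q] + d[p,q] (block offset + middle delta +
#' small delta, k = floor(p/32)).  The initial conditions live on the
#' phantom block k = -1 and its phantom vector at p = -1:
#' L[-1] = 0, D[q] = -GoH + |q - W/2| * -(M + GeH + GeV - 128/W),
#' d[-1,q] = |q - W/2| * -128/W.  The |q - W/2| terms incline the middle
#' delta away from the band centre at the steepest per-lane score drop, and
#' the 128/W counter-incline (exact for W = 32; truncating integer division
#' otherwise) keeps small deltas from drifting on low-identity regions.
#'
#' @param scheme a [ScoringScheme-class].
#' @param config a [BandConfig-class].
#' @return list with \code{L} (0), \code{D} (numeric W), \code{d}
#'   (numeric W, the phantom vector), \code{p} (-1) and \code{toprightI},
#'   the i-coordinate of lane q = 0 of the phantom vector.
#' @export
phantomInit <- function(scheme, config) {
  methods::validObject(config)
  W <- config@W
  q <- 0:(W - 1L)
  incl <- 128L %/% W
  M <- maxSub(scheme)
  list(L = 0,
       D = -scheme@GoH +
         abs(q - W %/% 2L) * -(M + scheme@GeH + scheme@GeV - incl),
       d = abs(q - W %/% 2L) * -incl,
       p = -1L,
       toprightI = W %/% 2L - 1L)
}

#' Choose the next band advance direction
#'
#' The forefront moves toward its higher-scoring edge so that the score
#' difference between the two edge cells stays small and the optimal path
#' stays near the band centre: right (toward larger i, the top-right lane's
#' side) when the top edge S_V[0] scores higher, down when the bottom edge
#' S_V[W-1] scores higher.  An exact tie alternates with the previous
#' direction, which preserves the zigzag walk along a perfect diagonal.
#' Boundary clamps override the comparison: when the band has reached the
#' right end of a (\code{forceDown}) it can only slide down, and at the
#' bottom end of b (\code{forceRight}) only right; when both clamps are
#' active the walk alternates into the corner.
#'
#' @param scoreTop,scoreBottom reconstructed absolute scores of lanes 0 and
#'   W-1 (use \code{-Inf} for an out-of-matrix edge lane).
#' @param prevDirection "right" or "down".
#' @param forceRight,forceDown logical boundary clamps.
#' @return "right" or "down".
#' @export
chooseDirection <- function(scoreTop, scoreBottom, prevDirection = "down",
                            forceRight = FALSE, forceDown = FALSE) {
  prev <- match.arg(prevDirection, c("right", "down"))
  dir <- .chooseDir(scoreTop, scoreBottom,
                    if (prev == "right") .RIGHT else .DOWN,
                    forceRight, forceDown)
  c("right", "down")[dir]
}

.chooseDir <- function(sTop, sBot, prevDir, forceRight, forceDown) {
  if (forceRight && !forceDown) return(.RIGHT)
  if (forceDown && !forceRight) return(.DOWN)
  if (forceRight && forceDown)
    return(if (prevDir == .RIGHT) .DOWN else .RIGHT)
  if (is.na(sTop)) sTop <- -Inf
  if (is.na(sBot)) sBot <- -Inf
  if (sTop > sBot) .RIGHT
  else if (sTop < sBot) .DOWN
  else if (prevDir == .RIGHT) .DOWN
  else .RIGHT
}

#' X-drop termination test
#'
#' @param forefrontBest best absolute score on the current forefront.
#' @param runningMax global running maximum.
#' @param config a [BandConfig-class].
#' @return TRUE iff \code{forefrontBest < runningMax - X} (strict: a drop
#'   of exactly X continues).
#' @export
xdropTerminate <- function(forefrontBest, runningMax, config) {
  isTRUE(forefrontBest < runningMax - config@X)
}

# Shared constants for the vectorized band step.
.bandConsts <- function(a, b, scheme, config) {
  W <- config@W
  offC <- scheme@GoH + scheme@GeH + scheme@GoV + scheme@GeV
  M <- maxSub(scheme)
  list(a = a, b = b, la = length(a), lb = length(b),
       W = W, blockLen = config@blockLen, X = config@X,
       deltaBits = config@deltaBits,
       GoH = scheme@GoH, GeH = scheme@GeH,
       GoV = scheme@GoV, GeV = scheme@GeV,
       ooH = scheme@GoH + scheme@GeH, ooV = scheme@GoV + scheme@GeV,
       tabG = subTable(scheme, offC),
       D = phantomInit(scheme, config)$D,
       # missing-neighbour substitute: low enough that a branch through it
       # can never win a maximum anywhere in the run
       K = (length(a) + length(b) + 2 * W + 64) * (M + offC + 1) + 1024)
}

# One forefront advance.  Reads only the immediately preceding forefront
# (the difference form removes the second-previous-vector dependence), so
# the whole engine state is the single `st` list.
#
# Lane geometry: lane q of the forefront at antidiagonal p holds cell
# (i, j) = (toprightI - q, p - toprightI + q); q = 0 is the top-right lane.
# A right move keeps [i-1,j]-indexed operands in the same lane and pulls
# [i,j-1] operands from lane q-1; a down move pulls [i-1,j] from lane q+1
# and keeps [i,j-1] in place.  Reads past the band edge substitute -K.
.bandStep <- function(st, dir, cs) {
  W <- cs$W; K <- cs$K
  p <- st$p + 1L
  tri <- st$tri + (dir == .RIGHT)
  i <- tri - 0:(W - 1L)
  j <- p - i
  if (dir == .RIGHT) {
    pE <- st$EG; pV <- st$VG
    pH <- c(-K, st$HG[-W]); pF <- c(-K, st$FG[-W])
  } else {
    pE <- c(st$EG[-1L], -K); pV <- c(st$VG[-1L], -K)
    pH <- st$HG; pF <- st$FG
  }
  interior <- i >= 1L & j >= 1L & i <= cs$la & j <= cs$lb
  ai <- pmin(pmax(i, 1L), cs$la)
  bj <- pmin(pmax(j, 1L), cs$lb)
  sv <- cs$tabG[4L * cs$a[ai] + cs$b[bj] + 1L]
  AG <- pmax(sv, pE, pF)
  HG <- AG - pV
  VG <- AG - pH
  EG <- pmax(AG, pE + cs$GoH) - pH
  FG <- pmax(AG, pF + cs$GoV) - pV
  d <- st$d + if (dir == .RIGHT) HG - cs$ooH else VG - cs$ooV
  fl <- .recordFlags(AG, pE, pF, cs$GoH, cs$GoV)
  fH <- interior & fl$mH
  fV <- interior & fl$mV
  fE <- interior & fl$mE
  fF <- interior & fl$mF
  inM <- interior
  top <- which(i == 0L)          # at most one lane: the i = 0 column
  if (length(top) && j[top] <= cs$lb) {
    jt <- j[top]
    if (jt == 0L) {              # the origin
      HG[top] <- VG[top] <- EG[top] <- FG[top] <- -K
      d[top] <- -st$L - cs$D[top]
    } else {
      VG[top] <- EG[top] <- if (jt == 1L) 0 else cs$GoV
      HG[top] <- FG[top] <- -K
      d[top] <- (-cs$GoV - jt * cs$GeV) - st$L - cs$D[top]
    }
    inM[top] <- TRUE
  }
  left <- which(j == 0L & i >= 1L)  # the j = 0 row
  if (length(left) && i[left] <= cs$la) {
    it <- i[left]
    HG[left] <- FG[left] <- if (it == 1L) 0 else cs$GoH
    VG[left] <- EG[left] <- -K
    d[left] <- (-cs$GoH - it * cs$GeH) - st$L - cs$D[left]
    inM[left] <- TRUE
  }
  outs <- !inM
  if (any(outs)) {
    HG[outs] <- VG[outs] <- EG[outs] <- FG[outs] <- -K
    d[outs] <- -K
  }
  if (!is.na(cs$deltaBits)) {
    lim <- 2^(cs$deltaBits - 1)
    if (any(inM & d > lim - 1))
      stop(sprintf(
        "small-delta overflow: value beyond the %d-bit range at p = %d",
        as.integer(cs$deltaBits), p))
    d[inM & d < -lim] <- -lim    # saturate: only already-lost lanes sink here
  }
  list(state = list(p = p, tri = tri, HG = HG, VG = VG, EG = EG, FG = FG,
                    d = d, inMat = inM, L = st$L),
       fH = fH, fV = fV, fE = fE, fF = fF)
}

.phantomState <- function(scheme, config, cs) {
  ph <- phantomInit(scheme, config)
  W <- config@W
  list(p = -1L, tri = ph$toprightI,
       HG = rep(-cs$K, W), VG = rep(-cs$K, W),
       EG = rep(-cs$K, W), FG = rep(-cs$K, W),
       d = ph$d, inMat = rep(FALSE, W), L = ph$L)
}

.sealDelta <- function(st, cs) {
  W <- cs$W
  vals <- cs$D + st$d
  pick <- function(q0) {
    if (st$inMat[q0 + 1L]) vals[q0 + 1L]
    else if (any(st$inMat)) max(vals[st$inMat])
    else 0
  }
  floor((pick(W %/% 4L) + pick(3L * W %/% 4L)) / 2)
}

#' Run the adaptive banded fill
#'
#' Advances a W-lane forefront from the origin across the DP matrix using
#' the offset difference recurrences, choosing right/down adaptively (see
#' [chooseDirection()]), recording traceback flags, sealing a block every
#' 32 vectors (rebasing the small deltas against the new large offset
#' L[k+1], the floor-average of the reconstructed lane W/4 and 3W/4 values
#' of the block's last vector), and terminating at the far corner or by
#' X-drop.
#'
#' @inheritParams fillReference
#' @param config a [BandConfig-class].
#' @param keepFlags record the four traceback flag matrices (needed by
#'   [tracebackBanded()]; switch off for fill-only diagnostics on large
#'   problems).
#' @param rebase apply the block-offset rebasing; \code{FALSE} keeps L = 0
#'   and wide small deltas throughout (diagnostic mode used to demonstrate
#'   rebase invariance).
#' @return a [BandResult-class].
#' @export
bandFill <- function(a, b, scheme = scoringScheme(), config = bandConfig(),
                     keepFlags = TRUE, rebase = TRUE) {
  methods::validObject(scheme); methods::validObject(config)
  a <- .asEncoded(a, "sequence a")
  b <- .asEncoded(b, "sequence b")
  cs <- .bandConsts(a, b, scheme, config)
  W <- cs$W
  Pmax <- cs$la + cs$lb
  st <- .phantomState(scheme, config, cs)
  toprightI <- integer(Pmax + 1L)
  directions <- integer(Pmax + 1L)
  flags <- if (keepFlags)
    list(mH = matrix(FALSE, W, Pmax + 1L), mV = matrix(FALSE, W, Pmax + 1L),
         mE = matrix(FALSE, W, Pmax + 1L), mF = matrix(FALSE, W, Pmax + 1L))
  else list()
  blocks <- vector("list", Pmax %/% cs$blockLen + 1L)
  nBlocks <- 0L
  blockStart <- st
  blockDirs <- integer(0L)
  blockMaxd <- rep(-Inf, W)
  globalMax <- -Inf
  prevDir <- .DOWN
  terminated <- "end"
  dlo <- Inf; dhi <- -Inf
  repeat {
    forceDown <- st$tri >= cs$la
    forceRight <- st$p - (st$tri - (W - 1L)) >= cs$lb
    sTop <- if (st$inMat[1L]) st$L + cs$D[1L] + st$d[1L] else -Inf
    sBot <- if (st$inMat[W]) st$L + cs$D[W] + st$d[W] else -Inf
    dir <- .chooseDir(sTop, sBot, prevDir, forceRight, forceDown)
    prevDir <- dir
    out <- .bandStep(st, dir, cs)
    st <- out$state
    p <- st$p
    toprightI[p + 1L] <- st$tri
    directions[p + 1L] <- dir
    if (keepFlags) {
      flags$mH[, p + 1L] <- out$fH; flags$mV[, p + 1L] <- out$fV
      flags$mE[, p + 1L] <- out$fE; flags$mF[, p + 1L] <- out$fF
    }
    blockDirs <- c(blockDirs, dir)
    live <- st$inMat
    if (any(live)) {
      blockMaxd[live] <- pmax(blockMaxd[live], st$d[live])
      rng <- range(st$d[live])
      dlo <- min(dlo, rng[1L]); dhi <- max(dhi, rng[2L])
      best <- st$L + max((cs$D + st$d)[live])
      if (best > globalMax) globalMax <- best
    } else {
      best <- NA_real_
    }
    xstop <- !is.na(best) && best < globalMax - cs$X
    lastStep <- p == Pmax || xstop
    if ((p + 1L) %% cs$blockLen == 0L || lastStep) {
      nBlocks <- nBlocks + 1L
      blocks[[nBlocks]] <- list(
        k = nBlocks - 1L, L = st$L, pEnd = p, triEnd = st$tri,
        start = blockStart, dirs = blockDirs,
        lastD = st$d, maxD = blockMaxd, inMat = st$inMat)
      if (!lastStep && rebase) {
        delta <- .sealDelta(st, cs)
        st$d <- st$d - delta
        st$L <- st$L + delta
      }
      blockStart <- st
      blockDirs <- integer(0L)
      blockMaxd <- rep(-Inf, W)
    }
    if (xstop) { terminated <- "xdrop"; break }
    if (p == Pmax) break
  }
  nSteps <- st$p
  mx <- .findMaxInternal(blocks[seq_len(nBlocks)], cs)
  methods::new("BandResult", a = a, b = b, scheme = scheme, config = config,
               D = cs$D,
               directions = directions[seq_len(nSteps + 1L)],
               toprightI = toprightI[seq_len(nSteps + 1L)],
               blocks = blocks[seq_len(nBlocks)], flags = flags,
               maxScore = mx$score, maxCell = c(mx$i, mx$j),
               nSteps = nSteps, terminated = terminated,
               deltaRange = c(dlo, dhi))
}

# Locate the maximum cell: block/lane candidates from L[k] + D[q] + maxD,
# then on-demand recomputation of the winning block's small-delta vectors
# from its stored boundary state and directions (advance is deterministic,
# so the refill is exact).  Ties resolve to smallest p = i + j, then
# smallest i, matching the reference argmax.
.findMaxInternal <- function(blocks, cs) {
  best <- -Inf; kBest <- NA_integer_
  for (bl in blocks) {
    v <- bl$L + max(cs$D + bl$maxD)
    if (v > best) { best <- v; kBest <- bl$k }
  }
  if (!is.finite(best))
    return(list(score = -Inf, i = NA_integer_, j = NA_integer_,
                p = NA_integer_, q = NA_integer_))
  bl <- blocks[[kBest + 1L]]
  st <- bl$start
  hit <- NULL
  for (dir in bl$dirs) {
    st <- .bandStep(st, dir, cs)$state
    sc <- bl$L + cs$D + st$d
    cand <- which(st$inMat & sc == best)
    if (length(cand)) {
      iC <- st$tri - (cand - 1L)
      o <- order(iC)[1L]             # smallest i
      hit <- list(score = best, i = iC[o], j = st$p - iC[o],
                  p = st$p, q = cand[o] - 1L)
      break                          # first vector with a hit: smallest p
    }
  }
  if (is.null(hit))
    stop("internal error: block refill failed to reproduce its maximum")
  hit
}

#' Find the maximum-score cell of a banded fill
#'
#' Maximizes L[k] + D[q] + max-small-delta over all sealed blocks and
#' lanes, then refills the winning block from its stored boundary vectors
#' to locate the exact antidiagonal.  In-matrix cells only; ties resolve to
#' smallest i + j then smallest i.
#'
#' @param res a [BandResult-class].
#' @return list with \code{score}, \code{i}, \code{j}, \code{p}, \code{q}.
#' @export
findMaxCell <- function(res) {
  cs <- .bandConsts(res@a, res@b, res@scheme, res@config)
  .findMaxInternal(res@blocks, cs)
}

setMethod("show", "BandResult", function(object) {
  cat(sprintf(
    "BandResult: |a| = %d, |b| = %d, W = %d, X = %g\n",
    length(object@a), length(object@b), object@config@W, object@config@X))
  cat(sprintf(
    "  %d antidiagonals, %d blocks, terminated at %s; max %g at (%d,%d)\n",
    object@nSteps + 1L, length(object@blocks), object@terminated,
    object@maxScore, object@maxCell[1L], object@maxCell[2L]))
  invisible(object)
})
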