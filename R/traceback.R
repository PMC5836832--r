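#' @include AllClasses.R band.R path.R
NULL

# Definitional core of the traceback flags, on offset difference values:
# the horizontal flag is set iff the E branch achieves the A_G maximum
# (S[i,j] -> E[i-1,j] is score-consistent), the vertical flag iff the F
# branch does; the gap-extension flags are set iff the extension branch
# achieves the inner maximum of the dE'_G / dF'_G recurrences
# (E[i,j] -> E[i-1,j] resp. F[i,j] -> F[i,j-1]).  Pure equality tests on
# difference values; no score reconstruction involved.
.recordFlags <- function(AG, gapHPrev, gapVPrev, GoH, GoV) {
  list(mH = AG == gapHPrev,
       mV = AG == gapVPrev,
       mE = gapHPrev + GoH >= AG,
       mF = gapVPrev + GoV >= AG)
}

#' Traceback flags from offset difference values
#'
#' Given the cell's A_G value and the offset gap operands it was computed
#' from (dE'_G of the left neighbour, dF'_G of the upper neighbour),
#' returns which transitions are score-consistent: \code{mH} for
#' S[i,j] -> E[i-1,j], \code{mV} for S[i,j] -> F[i,j-1], \code{mE} for
#' E[i,j] -> E[i-1,j] and \code{mF} for F[i,j] -> F[i,j-1].  Vectorized
#' over lanes; this is exactly the flag computation the banded fill
#' records per forefront.
#'
#' @param AG numeric, A_G of the cell(s).
#' @param gapHPrev numeric, dE'_G[i-1,j] operand(s).
#' @param gapVPrev numeric, dF'_G[i,j-1] operand(s).
#' @param scheme a [ScoringScheme-class].
#' @return list of four logical vectors mH, mV, mE, mF.
#' @export
recordFlags <- function(AG, gapHPrev, gapVPrev, scheme) {
  .recordFlags(AG, gapHPrev, gapVPrev, scheme@GoH, scheme@GoV)
}

#' Trace back through the band using recorded flags
#'
#' Walks from \code{start} to the origin by logic only, honouring the
#' strict transition priority: vertical over horizontal, diagonal only when
#' neither gap transition is flagged.  Gap runs are walked through the
#' mE/mF extension flags exactly as a nondifference affine traceback
#' would: a gap keeps extending while its extension flag permits and
#' closes (back to the S state, same cell) where it does not.  Cells on
#' the i = 0 / j = 0 edges force the only possible move.
#'
#' @param res a [BandResult-class] filled with \code{keepFlags = TRUE}.
#' @param start integer(2) cell (i,j); defaults to the band maximum.
#' @return a [PathString-class].
#' @export
tracebackBanded <- function(res, start = res@maxCell) {
  if (!length(res@flags))
    stop("band was filled with keepFlags = FALSE; no traceback flags")
  W <- res@config@W
  mH <- res@flags$mH; mV <- res@flags$mV
  mE <- res@flags$mE; mF <- res@flags$mF
  tri <- res@toprightI
  i <- as.integer(start[1L]); j <- as.integer(start[2L])
  if (is.na(i) || is.na(j))
    stop("banded result has no maximum cell to trace from")
  laneOf <- function(i, j) {
    p <- i + j
    if (p + 1L > length(tri)) stop("cell beyond the filled band")
    q <- tri[p + 1L] - i
    if (q < 0L || q >= W)
      stop(sprintf("band corruption: cell (%d,%d) is outside the band", i, j))
    q
  }
  trans <- integer(i + j)
  nt <- 0L
  state <- "S"
  while (i > 0L || j > 0L) {
    if (state == "S") {
      if (i == 0L) {
        nt <- nt + 1L; trans[nt] <- 1L; j <- j - 1L
      } else if (j == 0L) {
        nt <- nt + 1L; trans[nt] <- 2L; i <- i - 1L
      } else {
        q <- laneOf(i, j); p <- i + j
        if (mV[q + 1L, p + 1L]) {
          nt <- nt + 1L; trans[nt] <- 1L; j <- j - 1L; state <- "F"
        } else if (mH[q + 1L, p + 1L]) {
          nt <- nt + 1L; trans[nt] <- 2L; i <- i - 1L; state <- "E"
        } else {
          nt <- nt + 1L; trans[nt] <- 3L; i <- i - 1L; j <- j - 1L
        }
      }
    } else if (state == "E") {
      if (i > 0L && j > 0L) {
        q <- laneOf(i, j); p <- i + j
        if (mE[q + 1L, p + 1L]) {
          nt <- nt + 1L; trans[nt] <- 2L; i <- i - 1L
        } else state <- "S"
      } else state <- "S"
    } else {
      if (i > 0L && j > 0L) {
        q <- laneOf(i, j); p <- i + j
        if (mF[q + 1L, p + 1L]) {
          nt <- nt + 1L; trans[nt] <- 1L; j <- j - 1L
        } else state <- "S"
      } else state <- "S"
    }
  }
  .pathFromTraceback(trans[seq_len(nt)])
}
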