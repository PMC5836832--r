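#' @include AllClasses.R scoringScheme.R encode.R
NULL

# Sentinel used for the unreachable -inf edges of E (i = 0) and F (j = 0):
# at least (|a|+|b|) * (GoH+GeH+GoV+GeV) + M below zero, so it can never win
# a maximum in finite integer arithmetic.
.negSentinel <- function(la, lb, scheme) {
  pens <- scheme@GoH + scheme@GeH + scheme@GoV + scheme@GeV
  -((la + lb) * max(pens, 1) + abs(maxSub(scheme)) + 1)
}

#' Fill the nondifference semi-global DP matrices
#'
#' The classical affine-gap semi-global dynamic program: one alignment end
#' is fixed at the origin (0,0), the other is free, and the alignment score
#' is the matrix-wide maximum of S.  This is the reference oracle against
#' which the difference formulations and the banded engine are tested.
#'
#' Cells are filled antidiagonal by antidiagonal (the same geometry the
#' vectorized engines use), with
#' \deqn{S[i,j] = \max(S[i-1,j-1] + s(a_{i-1}, b_{j-1}),\;
#'                     E[i-1,j] - GeH,\; F[i,j-1] - GeV)}
#' \deqn{E[i,j] = \max(S[i,j] - GoH,\; E[i-1,j] - GeH)}
#' \deqn{F[i,j] = \max(S[i,j] - GoV,\; F[i,j-1] - GeV)}
#' and edges \code{S[i,0] = -GoH - i*GeH}, \code{S[0,j] = -GoV - j*GeV}.
#' Ties in every maximum resolve in the order written (diagonal, then E,
#' then F); the maximum cell tie-breaks toward smallest i + j, then
#' smallest i.
#'
#' @param a,b nucleotide strings or 2-bit-encoded integer vectors
#'   (non-empty).
#' @param scheme a [ScoringScheme-class].
#' @return a [FullDP-class].
#' @examples
#' dp <- fillReference("ACGT", "ACGT", scoringScheme())
#' dp@maxScore  # 4
#' @export
fillReference <- function(a, b, scheme = scoringScheme()) {
  methods::validObject(scheme)
  a <- .asEncoded(a, "sequence a")
  b <- .asEncoded(b, "sequence b")
  la <- length(a); lb <- length(b)
  GoH <- scheme@GoH; GeH <- scheme@GeH; GoV <- scheme@GoV; GeV <- scheme@GeV
  NEG <- .negSentinel(la, lb, scheme)
  nr <- la + 1L
  S <- matrix(NA_real_, nr, lb + 1L)
  E <- matrix(NA_real_, nr, lb + 1L)
  F <- matrix(NA_real_, nr, lb + 1L)
  S[1L, ] <- c(0, -GoV - seq_len(lb) * GeV)
  S[, 1L] <- c(0, -GoH - seq_len(la) * GeH)
  E[, 1L] <- -GoH - (0:la) * GeH          # E edge at j = 0 (includes E[0,0])
  E[1L, -1L] <- NEG                       # E edge at i = 0 is -inf
  F[1L, ] <- c(-GoV, -GoV - seq_len(lb) * GeV)
  F[-1L, 1L] <- NEG                       # F edge at j = 0 is -inf
  tab <- subTable(scheme)
  for (p in 2:(la + lb)) {
    ii <- max(1L, p - lb):min(la, p - 1L)
    jj <- p - ii
    linC <- ii + 1L + jj * nr
    linD <- ii + (jj - 1L) * nr
    linL <- ii + jj * nr
    linU <- ii + 1L + (jj - 1L) * nr
    sv <- tab[4L * a[ii] + b[jj] + 1L]
    Sv <- pmax(S[linD] + sv, E[linL] - GeH, F[linU] - GeV)
    S[linC] <- Sv
    E[linC] <- pmax(Sv - GoH, E[linL] - GeH)
    F[linC] <- pmax(Sv - GoV, F[linU] - GeV)
  }
  mc <- .argmaxCell(S, nr)
  methods::new("FullDP", a = a, b = b, scheme = scheme,
               S = S, E = E, F = F,
               maxScore = S[mc[1L] + 1L, mc[2L] + 1L], maxCell = mc,
               neg = NEG)
}

# argmax over an (la+1) x (lb+1) score matrix with the documented tie-break:
# smallest p = i + j, then smallest i.
.argmaxCell <- function(S, nr) {
  cand <- which(S == max(S))
  i <- (cand - 1L) %% nr
  j <- (cand - 1L) %/% nr
  o <- order(i + j, i)[1L]
  c(i[o], j[o])
}

#' Maximum semi-global score without storing the matrices
#'
#' Rolling-antidiagonal evaluation of the same recurrences as
#' [fillReference()], keeping only two antidiagonals in memory.  Used to
#' compare banded scores against the full dynamic program on sequence pairs
#' whose full matrices would be large.
#'
#' @inheritParams fillReference
#' @return numeric(1) the matrix-wide maximum of S.
#' @export
referenceScore <- function(a, b, scheme = scoringScheme()) {
  a <- .asEncoded(a, "sequence a")
  b <- .asEncoded(b, "sequence b")
  la <- length(a); lb <- length(b)
  GoH <- scheme@GoH; GeH <- scheme@GeH; GoV <- scheme@GoV; GeV <- scheme@GeV
  NEG <- .negSentinel(la, lb, scheme)
  tab <- subTable(scheme)
  # lane index is i (position i + 1); lane i of antidiagonal p is cell
  # (i, p - i)
  n <- la + 1L
  Spp <- rep(NA_real_, n); Sp <- Spp; Ep <- Spp; Fp <- Spp
  Spp[1L] <- 0
  if (la >= 1L) Sp[2L] <- -GoH - GeH
  Sp[1L] <- if (lb >= 1L) -GoV - GeV else NA_real_
  Ep[2L] <- if (la >= 1L) -GoH - GeH else NA_real_
  Ep[1L] <- NEG
  Fp[1L] <- if (lb >= 1L) -GoV - GeV else NA_real_
  Fp[2L] <- NEG
  best <- max(0, Sp, na.rm = TRUE)
  if (la + lb < 2L) return(best)
  for (p in 2:(la + lb)) {
    ii <- max(1L, p - lb):min(la, p - 1L)
    idx <- ii + 1L
    sv <- tab[4L * a[ii] + b[p - ii] + 1L]
    Sv <- pmax(Spp[idx - 1L] + sv, Ep[idx - 1L] - GeH, Fp[idx] - GeV)
    Ev <- pmax(Sv - GoH, Ep[idx - 1L] - GeH)
    Fv <- pmax(Sv - GoV, Fp[idx] - GeV)
    S2 <- Sp; Sp[] <- NA_real_; Ep2 <- rep(NA_real_, n); Fp2 <- Ep2
    Sp[idx] <- Sv; Ep2[idx] <- Ev; Fp2[idx] <- Fv
    # matrix edges of antidiagonal p
    if (p <= lb) {
      Sp[1L] <- -GoV - p * GeV; Ep2[1L] <- NEG; Fp2[1L] <- -GoV - p * GeV
    }
    if (p <= la) {
      Sp[p + 1L] <- -GoH - p * GeH; Ep2[p + 1L] <- -GoH - p * GeH
      Fp2[p + 1L] <- NEG
    }
    Spp <- S2; Ep <- Ep2; Fp <- Fp2
    best <- max(best, Sp, na.rm = TRUE)
  }
  best
}

#' Trace back an alignment path from the nondifference matrices
#'
#' Walks from \code{start} to the origin, preferring a vertical transition
#' over a horizontal one and a diagonal transition only when neither gap
#' transition is score-consistent -- the same priority the flag-based banded
#' traceback uses, so paths from the two engines are directly comparable.
#' Gap runs are walked through the E/F matrices exactly as an affine-gap
#' traceback must: once a gap is entered it is extended while the extension
#' branch is score-consistent, and closed where the gap-open branch holds.
#'
#' @param dp a [FullDP-class].
#' @param start integer(2) cell (i,j) to start from; defaults to the
#'   maximum cell.
#' @return a [PathString-class] in alignment order ("1" vertical, "0"
#'   horizontal, "10" diagonal).
#' @examples
#' dp <- fillReference("ACGT", "ACGT", scoringScheme())
#' pathChars(tracebackReference(dp))  # "10101010"
#' @export
tracebackReference <- function(dp, start = dp@maxCell) {
  S <- dp@S; E <- dp@E; F <- dp@F
  scheme <- dp@scheme
  GoH <- scheme@GoH; GeH <- scheme@GeH; GoV <- scheme@GoV; GeV <- scheme@GeV
  tab <- subTable(scheme)
  a <- dp@a; b <- dp@b
  i <- as.integer(start[1L]); j <- as.integer(start[2L])
  if (i < 0L || j < 0L || i > length(a) || j > length(b))
    stop("'start' is not a cell of the DP matrix")
  trans <- integer(i + j)   # 1 = vertical, 2 = horizontal, 3 = diagonal
  nt <- 0L
  state <- "S"
  while (i > 0L || j > 0L) {
    r <- i + 1L; c <- j + 1L
    if (state == "S") {
      if (i == 0L) {
        nt <- nt + 1L; trans[nt] <- 1L; j <- j - 1L
      } else if (j == 0L) {
        nt <- nt + 1L; trans[nt] <- 2L; i <- i - 1L
      } else if (S[r, c] == F[r, c - 1L] - GeV) {
        nt <- nt + 1L; trans[nt] <- 1L; j <- j - 1L; state <- "F"
      } else if (S[r, c] == E[r - 1L, c] - GeH) {
        nt <- nt + 1L; trans[nt] <- 2L; i <- i - 1L; state <- "E"
      } else if (S[r, c] == S[r - 1L, c - 1L] +
                 tab[4L * a[i] + b[j] + 1L]) {
        nt <- nt + 1L; trans[nt] <- 3L; i <- i - 1L; j <- j - 1L
      } else {
        stop(sprintf(
          "inconsistent DP matrices: no score-consistent predecessor at (%d,%d)",
          i, j))
      }
    } else if (state == "E") {
      if (i > 0L && E[r, c] == E[r - 1L, c] - GeH) {
        nt <- nt + 1L; trans[nt] <- 2L; i <- i - 1L
      } else if (E[r, c] == S[r, c] - GoH) {
        state <- "S"
      } else {
        stop(sprintf("inconsistent E matrix at (%d,%d)", i, j))
      }
    } else {
      if (j > 0L && F[r, c] == F[r, c - 1L] - GeV) {
        nt <- nt + 1L; trans[nt] <- 1L; j <- j - 1L
      } else if (F[r, c] == S[r, c] - GoV) {
        state <- "S"
      } else {
        stop(sprintf("inconsistent F matrix at (%d,%d)", i, j))
      }
    }
  }
  .pathFromTraceback(trans[seq_len(nt)])
}

setMethod("show", "FullDP", function(object) {
  cat(sprintf("FullDP: |a| = %d, |b| = %d; max score %g at (%d,%d)\n",
              length(object@a), length(object@b), object@maxScore,
              object@maxCell[1L], object@maxCell[2L]))
  invisible(object)
})
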