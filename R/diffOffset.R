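#' @include AllClasses.R diffNaive.R
NULL

#' Fill the offset difference matrices
#'
#' The affine-shifted form of the difference recurrences.  With
#' C = GoH + GeH + GoV + GeV and the precomputed offset substitution table
#' sG(x,y) = s(x,y) + C, the matrices
#' \deqn{A_G = A + C,\quad dH_G = dH + GoH + GeH,\quad dV_G = dV + GoV + GeV}
#' \deqn{dE'_G = dE + dV + GoH + GoV + GeV,\quad
#'       dF'_G = dF + dH + GoV + GoH + GeH}
#' obey the recurrences
#' \deqn{A_G = \max(s_G,\; dE'_G[i-1,j],\; dF'_G[i,j-1])}
#' \deqn{dH_G = A_G - dV_G[i-1,j], \quad dV_G = A_G - dH_G[i,j-1]}
#' \deqn{dE'_G = \max(A_G,\; dE'_G[i-1,j] + GoH) - dH_G[i,j-1]}
#' \deqn{dF'_G = \max(A_G,\; dF'_G[i,j-1] + GoV) - dV_G[i-1,j]}
#' whose values all lie in [0, M + C]: a single unsigned range, and a
#' per-cell critical path of 4 basic binary operations (see
#' [criticalPathLength()]).  Edge cells are the naive initial conditions
#' plus the offsets.
#'
#' @inheritParams fillReference
#' @return an [OffsetDiffState-class].
#' @seealso [toNaive()] for the exact inverse transformation.
#' @export
fillDiffOffset <- function(a, b, scheme = scoringScheme()) {
  methods::validObject(scheme)
  a <- .asEncoded(a, "sequence a")
  b <- .asEncoded(b, "sequence b")
  la <- length(a); lb <- length(b)
  GoH <- scheme@GoH; GeH <- scheme@GeH; GoV <- scheme@GoV; GeV <- scheme@GeV
  offC <- GoH + GeH + GoV + GeV
  nr <- la + 1L
  dHG <- matrix(NA_real_, nr, lb + 1L)
  dVG <- matrix(NA_real_, nr, lb + 1L)
  dEG <- matrix(NA_real_, nr, lb + 1L)
  dFG <- matrix(NA_real_, nr, lb + 1L)
  AG <- matrix(NA_real_, nr, lb + 1L)
  # naive initial conditions plus offsets
  dHG[-1L, 1L] <- c(0, rep(GoH, la - 1L))
  dVG[1L, -1L] <- c(0, rep(GoV, lb - 1L))
  dEG[1L, -1L] <- c(0, rep(GoV, lb - 1L))
  dFG[-1L, 1L] <- c(0, rep(GoH, la - 1L))
  sG <- matrix(subTable(scheme, offC), 4L, 4L, byrow = TRUE)
  tabG <- subTable(scheme, offC)
  for (p in 2:(la + lb)) {
    ii <- max(1L, p - lb):min(la, p - 1L)
    jj <- p - ii
    linC <- ii + 1L + jj * nr
    linL <- ii + jj * nr
    linU <- ii + 1L + (jj - 1L) * nr
    sv <- tabG[4L * a[ii] + b[jj] + 1L]
    AGv <- pmax(sv, dEG[linL], dFG[linU])
    AG[linC] <- AGv
    dHG[linC] <- AGv - dVG[linL]
    dVG[linC] <- AGv - dHG[linU]
    dEG[linC] <- pmax(AGv, dEG[linL] + GoH) - dHG[linU]
    dFG[linC] <- pmax(AGv, dFG[linU] + GoV) - dVG[linL]
  }
  methods::new("OffsetDiffState", a = a, b = b, scheme = scheme,
               dHG = dHG, dVG = dVG, dEG = dEG, dFG = dFG, AG = AG,
               sG = sG)
}

#' Back-transform offset differences to the naive form
#'
#' Applies the exact inverses of the four offset identities; composed with
#' [fillDiffOffset()] this reproduces [fillDiffNaive()] cellwise, and
#' through [reconstructAbsolute()] the full absolute matrices.
#'
#' @param st an [OffsetDiffState-class].
#' @return a [NaiveDiffState-class].
#' @export
toNaive <- function(st) {
  scheme <- st@scheme
  GoH <- scheme@GoH; GeH <- scheme@GeH; GoV <- scheme@GoV; GeV <- scheme@GeV
  la <- length(st@a); lb <- length(st@b)
  offC <- GoH + GeH + GoV + GeV
  dH <- st@dHG - (GoH + GeH)
  dV <- st@dVG - (GoV + GeV)
  dE <- st@dEG - dV - (GoH + GoV + GeV)
  dF <- st@dFG - dH - (GoV + GoH + GeH)
  # edges where the offset form has no counterpart carry the naive values
  dE[, 1L] <- 0
  dF[1L, ] <- 0
  A <- st@AG - offC
  methods::new("NaiveDiffState", a = st@a, b = st@b, scheme = scheme,
               dH = dH, dV = dV, dE = dE, dF = dF, A = A)
}

#' Upper bound constant of the offset form
#'
#' All offset difference values lie in [0, M + GoH + GeH + GoV + GeV].
#'
#' @param scheme a [ScoringScheme-class].
#' @return numeric(1).
#' @export
offsetBound <- function(scheme) {
  maxSub(scheme) + scheme@GoH + scheme@GeH + scheme@GoV + scheme@GeV
}

setMethod("show", "OffsetDiffState", function(object) {
  cat(sprintf(
    "OffsetDiffState: |a| = %d, |b| = %d; values in [0, %g]\n",
    length(object@a), length(object@b), offsetBound(object@scheme)))
  invisible(object)
})
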