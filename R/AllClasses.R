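#' @import methods
NULL

#' Affine-gap scoring scheme for nucleotide alignment
#'
#' Holds the 4x4 substitution table \code{s(x,y)} (indexed by 2-bit-encoded
#' bases A=0, C=1, G=2, T=3) and the four non-negative gap penalty magnitudes.
#' Penalties are subtracted from scores: a horizontal gap of length k costs
#' \code{GoH + k * GeH}, a vertical gap \code{GoV + k * GeV}.  Horizontal
#' transitions consume the first ("reference-like") sequence, vertical
#' transitions the second.
#'
#' Validity requires \code{max(sub) >= 0}, strictly positive gap-extension
#' penalties, and \code{min(sub) > -(GoH + GeH + GoV + GeV)}.
#'
#' @slot sub numeric 4x4 substitution matrix, rows = base of sequence a,
#'   columns = base of sequence b (score units).
#' @slot GoH,GeH,GoV,GeV numeric(1) gap-open / gap-extension penalty
#'   magnitudes (score units, non-negative; extensions strictly positive).
#' @seealso [scoringScheme()]
#' @exportClass ScoringScheme
setClass("ScoringScheme",
  representation(
    sub = "matrix",
    GoH = "numeric", GeH = "numeric",
    GoV = "numeric", GeV = "numeric"
  )
)

setValidity("ScoringScheme", function(object) {
  msg <- character()
  if (!is.numeric(object@sub) || !all(dim(object@sub) == c(4L, 4L)))
    msg <- c(msg, "'sub' must be a numeric 4x4 matrix")
  pens <- c(object@GoH, object@GeH, object@GoV, object@GeV)
  if (length(pens) != 4L || any(!is.finite(pens)))
    msg <- c(msg, "gap penalties must be finite scalars")
  else {
    if (any(pens < 0))
      msg <- c(msg, "gap penalties are magnitudes and must be non-negative")
    if (object@GeH <= 0 || object@GeV <= 0)
      msg <- c(msg, "gap-extension penalties must be strictly positive")
    if (is.numeric(object@sub) && all(dim(object@sub) == c(4L, 4L))) {
      if (max(object@sub) < 0)
        msg <- c(msg, "the maximum substitution score M must be non-negative")
      if (min(object@sub) <= -sum(pens))
        msg <- c(msg,
          "min substitution score must exceed -(GoH + GeH + GoV + GeV)")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Full nondifference semi-global DP matrices
#'
#' Result of [fillReference()]: the S/E/F matrices of the classical
#' affine-gap semi-global dynamic program, the matrix-wide maximum of S and
#' its cell.  Matrices are (|a|+1) x (|b|+1); row r / column c store cell
#' (i,j) = (r-1, c-1), where cell (i,j) consumes a[0..i) and b[0..j)
#' (0-based half-open).  The unreachable edge cells of E (i = 0) and F
#' (j = 0) hold the finite sentinel \code{neg}, chosen low enough that it
#' can never win a maximum.
#'
#' @slot a,b integer vectors, 2-bit-encoded sequences.
#' @slot scheme the [ScoringScheme-class] used.
#' @slot S,E,F numeric matrices (score units).
#' @slot maxScore numeric(1) matrix-wide maximum of S.
#' @slot maxCell integer(2) its (i,j) location; ties broken toward smallest
#'   i + j, then smallest i.
#' @slot neg numeric(1) the -inf sentinel used on the E/F edges.
#' @exportClass FullDP
setClass("FullDP",
  representation(
    a = "integer", b = "integer", scheme = "ScoringScheme",
    S = "matrix", E = "matrix", F = "matrix",
    maxScore = "numeric", maxCell = "integer", neg = "numeric"
  )
)

#' Naive difference matrices
#'
#' Result of [fillDiffNaive()]: differences between adjacent cells of the
#' semi-global DP matrix S and the gap-matrix offsets, plus the diagonal
#' intermediate A.  Entries that are undefined by construction (dH at i = 0,
#' dV at j = 0, A on the edges) are NA.
#'
#' @slot a,b integer encoded sequences.
#' @slot scheme the [ScoringScheme-class] used.
#' @slot dH numeric matrix, S[i,j] - S[i-1,j] (defined for i >= 1).
#' @slot dV numeric matrix, S[i,j] - S[i,j-1] (defined for j >= 1).
#' @slot dE numeric matrix, E[i,j] - S[i,j]; the -inf edge at i = 0 is
#'   clipped to -GoH.
#' @slot dF numeric matrix, F[i,j] - S[i,j]; the -inf edge at j = 0 is
#'   clipped to -GoV.
#' @slot A numeric matrix, S[i,j] - S[i-1,j-1] (interior only).
#' @exportClass NaiveDiffState
setClass("NaiveDiffState",
  representation(
    a = "integer", b = "integer", scheme = "ScoringScheme",
    dH = "matrix", dV = "matrix", dE = "matrix", dF = "matrix", A = "matrix"
  )
)

#' Offset difference matrices
#'
#' Result of [fillDiffOffset()]: the affine-shifted difference matrices whose
#' values are all non-negative and bounded by the single constant
#' M + GoH + GeH + GoV + GeV, plus the offset substitution table sG.
#'
#' @slot a,b integer encoded sequences.
#' @slot scheme the [ScoringScheme-class] used.
#' @slot dHG,dVG,dEG,dFG,AG numeric matrices (offset form; NA where
#'   undefined).
#' @slot sG numeric 4x4 offset substitution table,
#'   \code{s(x,y) + GoH + GeH + GoV + GeV}.
#' @exportClass OffsetDiffState
setClass("OffsetDiffState",
  representation(
    a = "integer", b = "integer", scheme = "ScoringScheme",
    dHG = "matrix", dVG = "matrix", dEG = "matrix", dFG = "matrix",
    AG = "matrix", sG = "matrix"
  )
)

#' Adaptive band configuration
#'
#' @slot W integer(1) band width in lanes; even, >= 2.  Default 32.
#' @slot X numeric(1) X-drop threshold (score units, > 0).
#' @slot blockLen integer(1) vectors per block, fixed at 32.
#' @slot deltaBits numeric(1) nominal signed bit width emulated for the
#'   small-delta values; NA (default) disables narrow-width emulation and
#'   computes in wide arithmetic.  When set (e.g. 8), a positive overflow of
#'   a live lane raises an error and negative underflow saturates, matching
#'   saturating SIMD semantics.
#' @exportClass BandConfig
setClass("BandConfig",
  representation(W = "integer", X = "numeric", blockLen = "integer",
                 deltaBits = "numeric")
)

setValidity("BandConfig", function(object) {
  msg <- character()
  if (length(object@W) != 1L || object@W < 2L || object@W %% 2L != 0L)
    msg <- c(msg, "band width W must be a single even integer >= 2")
  if (length(object@X) != 1L || !is.finite(object@X) || object@X <= 0)
    msg <- c(msg, "X-drop threshold X must be a single positive number")
  if (!identical(object@blockLen, 32L))
    msg <- c(msg, "blockLen is fixed at 32 vectors per block")
  if (length(msg)) msg else TRUE
})

#' Banded alignment engine state
#'
#' Raw result of [bandFill()]: the direction sequence, per-step top-right
#' lane coordinates, sealed block records (large offsets L[k], last and
#' maximal small-delta vectors, boundary state for on-demand refill),
#' traceback flag matrices, and the matrix-wide maximum found in the band.
#'
#' @slot a,b integer encoded sequences.
#' @slot scheme the [ScoringScheme-class] used.
#' @slot config the [BandConfig-class] used.
#' @slot D numeric(W) middle-delta table (per-lane constant offset).
#' @slot directions integer vector, 1 = right, 2 = down, per advance.
#' @slot toprightI integer vector, i-coordinate of lane q = 0 per
#'   antidiagonal p (index p + 1, p = 0..nSteps).
#' @slot blocks list of sealed (and one trailing partial) block records.
#' @slot flags list of four logical W x (nSteps+1) matrices (mH, mV, mE, mF)
#'   when flag recording is enabled, else empty.
#' @slot maxScore numeric(1) best absolute score over in-matrix band cells.
#' @slot maxCell integer(2) its (i,j); ties toward smallest i + j then
#'   smallest i, matching the reference engine.
#' @slot nSteps integer(1) last antidiagonal computed.
#' @slot terminated character(1), "end" or "xdrop".
#' @slot deltaRange numeric(2) observed small-delta range over live lanes.
#' @exportClass BandResult
setClass("BandResult",
  representation(
    a = "integer", b = "integer", scheme = "ScoringScheme",
    config = "BandConfig", D = "numeric",
    directions = "integer", toprightI = "integer",
    blocks = "list", flags = "list",
    maxScore = "numeric", maxCell = "integer",
    nSteps = "integer", terminated = "character", deltaRange = "numeric"
  )
)

#' Bit-encoded alignment path
#'
#' Alignment-order bit encoding of an alignment path: "1" is a vertical
#' transition (consumes one base of b), "0" a horizontal transition
#' (consumes one base of a), and the two-bit word "10" a diagonal transition
#' (match or mismatch).  Under the traceback priority vertical > horizontal
#' > diagonal the encoding is uniquely decodable in both reading directions.
#'
#' @slot bits integer vector of 0/1 in alignment order (origin to end).
#' @exportClass PathString
setClass("PathString", representation(bits = "integer"))

setValidity("PathString", function(object) {
  if (length(object@bits) && !all(object@bits %in% c(0L, 1L)))
    "path bits must all be 0 or 1" else TRUE
})

#' Run-length CIGAR
#'
#' @slot ops character vector over {"M","I","D"}; adjacent ops differ.
#' @slot lengths integer vector of run lengths (>= 1).
#' @exportClass Cigar
setClass("Cigar", representation(ops = "character", lengths = "integer"))

setValidity("Cigar", function(object) {
  msg <- character()
  if (length(object@ops) != length(object@lengths))
    msg <- c(msg, "ops and lengths must have equal length")
  if (!all(object@ops %in% c("M", "I", "D")))
    msg <- c(msg, "ops must be M, I or D")
  if (any(object@lengths < 1L))
    msg <- c(msg, "run lengths must be >= 1")
  if (length(object@ops) > 1L &&
      any(object@ops[-1L] == object@ops[-length(object@ops)]))
    msg <- c(msg, "adjacent CIGAR ops must differ")
  if (length(msg)) msg else TRUE
})

#' Complete pairwise alignment result
#'
#' @slot score numeric(1) alignment score (the DP maximum).
#' @slot endCell integer(2) (i,j) end of the alignment; the start is fixed
#'   at the origin (0,0).
#' @slot path a [PathString-class].
#' @slot cigar a [Cigar-class].
#' @slot engine character(1), one of "reference", "naive", "offset",
#'   "banded".
#' @exportClass AlignmentResult
setClass("AlignmentResult",
  representation(score = "numeric", endCell = "integer",
                 path = "PathString", cigar = "Cigar", engine = "character")
)
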