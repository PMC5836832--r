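#' @include AllClasses.R AllGenerics.R
NULL

#' Construct an affine-gap scoring scheme
#'
#' Either give \code{match}/\code{mismatch} scores (a uniform 4x4 table is
#' built) or a full 4x4 substitution matrix via \code{sub}.  Gap penalties
#' are magnitudes and are subtracted during alignment.  The defaults are the
#' unit long-read scheme: match 1, mismatch -1, gap open 1, gap extension 1
#' for both orientations.
#'
#' @param match,mismatch numeric(1) substitution scores used when
#'   \code{sub} is NULL.
#' @param gapOpenH,gapExtendH,gapOpenV,gapExtendV numeric(1) penalty
#'   magnitudes for horizontal (consuming sequence a) and vertical
#'   (consuming sequence b) gaps.
#' @param gapOpen,gapExtend convenience scalars setting both orientations
#'   at once; overridden by the orientation-specific arguments.
#' @param sub optional numeric 4x4 substitution matrix indexed by
#'   2-bit-encoded bases (A=0 ... T=3).
#' @return a validated [ScoringScheme-class].
#' @examples
#' scoringScheme()                           # unit scheme 1/-1/1/1
#' scoringScheme(match = 2, mismatch = -2, gapOpen = 4, gapExtend = 1)
#' @export
scoringScheme <- function(match = 1, mismatch = -1,
                          gapOpen = 1, gapExtend = 1,
                          gapOpenH = gapOpen, gapExtendH = gapExtend,
                          gapOpenV = gapOpen, gapExtendV = gapExtend,
                          sub = NULL) {
  if (is.null(sub)) {
    sub <- matrix(as.numeric(mismatch), 4L, 4L)
    diag(sub) <- as.numeric(match)
  } else {
    sub <- matrix(as.numeric(sub), 4L, 4L)
  }
  dimnames(sub) <- list(c("A", "C", "G", "T"), c("A", "C", "G", "T"))
  methods::new("ScoringScheme", sub = sub,
               GoH = as.numeric(gapOpenH), GeH = as.numeric(gapExtendH),
               GoV = as.numeric(gapOpenV), GeV = as.numeric(gapExtendV))
}

#' @describeIn scoringScheme maximum entry M of the substitution table.
#' @param x a \code{ScoringScheme}.
#' @export
setMethod("maxSub", "ScoringScheme", function(x) max(x@sub))

#' Flattened 16-entry substitution lookup
#'
#' Returns the substitution table as a length-16 vector keyed by
#' \code{4 * code(a) + code(b) + 1}, the precomputed-lookup form used by the
#' fill engines (the table-lookup analogue of a vector shuffle).
#'
#' @param scheme a [ScoringScheme-class].
#' @param offset numeric(1) added to every entry (used for the offset
#'   substitution table sG).
#' @return numeric(16).
#' @export
subTable <- function(scheme, offset = 0) {
  as.numeric(t(scheme@sub)) + offset
}

# s(a_i, b_j) for encoded vectors via the 16-entry lookup
.subLookup <- function(tab, acode, bcode) tab[4L * acode + bcode + 1L]

setMethod("show", "ScoringScheme", function(object) {
  cat("ScoringScheme\n")
  cat(sprintf("  M = %g; gaps H: open %g extend %g | V: open %g extend %g\n",
              max(object@sub), object@GoH, object@GeH,
              object@GoV, object@GeV))
  m <- object@sub
  is_unit <- all(diag(m) == m[1, 1]) &&
    all(m[row(m) != col(m)] == m[1, 2])
  if (is_unit) {
    cat(sprintf("  substitution: match %g / mismatch %g\n", m[1, 1], m[1, 2]))
  } else {
    cat("  substitution table:\n")
    print(m)
  }
  invisible(object)
})
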