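#' @include AllClasses.R reference.R diffNaive.R diffOffset.R band.R traceback.R cigar.R
NULL

#' Align a pair of sequences end to end
#'
#' Runs one of the four engines and returns score, end cell, bit-encoded
#' path and CIGAR.  All engines share the origin-anchored semi-global
#' model and the vertical > horizontal > diagonal traceback priority, so
#' their outputs are directly comparable; "naive" and "offset" fill the
#' difference matrices and reconstruct the absolute matrices before the
#' traceback, "banded" runs the adaptive banded engine and its flag-based
#' traceback.
#'
#' @inheritParams fillReference
#' @param engine "reference", "naive", "offset" or "banded".
#' @param config a [BandConfig-class] (banded engine only).
#' @return an [AlignmentResult-class].
#' @examples
#' r <- alignPair("ACGTACGT", "ACGGACGT")
#' alignmentScore(r)
#' cigarString(r)
#' @export
alignPair <- function(a, b, scheme = scoringScheme(),
                      engine = c("reference", "naive", "offset", "banded"),
                      config = bandConfig()) {
  engine <- match.arg(engine)
  if (engine == "banded") {
    res <- bandFill(a, b, scheme, config, keepFlags = TRUE)
    path <- tracebackBanded(res)
    return(methods::new("AlignmentResult",
                        score = res@maxScore, endCell = res@maxCell,
                        path = path, cigar = pathToCigar(path),
                        engine = engine))
  }
  dp <- switch(engine,
    reference = fillReference(a, b, scheme),
    naive = reconstructAbsolute(fillDiffNaive(a, b, scheme)),
    offset = reconstructAbsolute(toNaive(fillDiffOffset(a, b, scheme))))
  path <- tracebackReference(dp)
  methods::new("AlignmentResult",
               score = dp@maxScore, endCell = dp@maxCell,
               path = path, cigar = pathToCigar(path), engine = engine)
}

#' @describeIn alignPair score accessor.
#' @param x an \code{AlignmentResult}.
#' @export
setMethod("alignmentScore", "AlignmentResult", function(x) x@score)

#' @describeIn alignPair CIGAR accessor.
#' @export
setMethod("cigar", "AlignmentResult", function(x) x@cigar)

#' @describeIn alignPair SAM CIGAR string of the alignment.
#' @export
setMethod("cigarString", "AlignmentResult", function(x) cigarString(x@cigar))

#' @describeIn alignPair path accessor.
#' @export
setMethod("alignmentPath", "AlignmentResult", function(x) x@path)

#' @describeIn alignPair path bit accessor.
#' @export
setMethod("pathBits", "AlignmentResult", function(x) x@path@bits)

setMethod("show", "AlignmentResult", function(object) {
  cat(sprintf("AlignmentResult (%s engine)\n", object@engine))
  cat(sprintf("  score %g, end (%d,%d), CIGAR %s\n",
              object@score, object@endCell[1L], object@endCell[2L],
              if (length(object@cigar@ops)) cigarString(object@cigar)
              else "<empty>"))
  invisible(object)
})
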