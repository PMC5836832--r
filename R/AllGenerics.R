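#' @include AllClasses.R
NULL

#' Maximum substitution score of a scheme
#'
#' @param x a [ScoringScheme-class].
#' @return numeric(1), \code{M = max(sub)}.
#' @export
setGeneric("maxSub", function(x) standardGeneric("maxSub"))

#' Alignment score accessor
#' @param x an alignment-bearing object.
#' @export
setGeneric("alignmentScore", function(x) standardGeneric("alignmentScore"))

#' Cigar accessor
#' @param x an object carrying a CIGAR.
#' @export
setGeneric("cigar", function(x) standardGeneric("cigar"))

#' SAM-grammar CIGAR string
#' @param x a [Cigar-class] or an object carrying one.
#' @export
setGeneric("cigarString", function(x) standardGeneric("cigarString"))

#' Alignment path accessor
#' @param x an object carrying a bit-encoded path.
#' @export
setGeneric("alignmentPath", function(x) standardGeneric("alignmentPath"))

#' Path bits accessor
#' @param x a [PathString-class] or an object carrying one.
#' @export
setGeneric("pathBits", function(x) standardGeneric("pathBits"))
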