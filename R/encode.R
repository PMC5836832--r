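#' @include AllClasses.R
NULL

#' Encode a nucleotide string into 2-bit integers
#'
#' Maps A->0, C->1, G->2, T->3 (case-insensitively).  The 2-bit encoding is
#' the working representation of all alignment engines in the package: the
#' substitution score of a base pair (x, y) is looked up in a precomputed
#' 16-entry table keyed by \code{4 * x + y}.
#'
#' Ambiguity codes are rejected: alignment over {A,C,G,T} is the supported
#' domain and the first offending position is named in the error.
#'
#' @param text a single non-empty character string (or a
#'   \code{Biostrings::DNAString}); characters outside ACGT/acgt are an
#'   error.
#' @return integer vector of values in 0..3.
#' @examples
#' encodeSequence("ACGT")   # 0 1 2 3
#' encodeSequence("acgt")   # 0 1 2 3
#' @export
encodeSequence <- function(text) {
  if (methods::is(text, "XString") || methods::is(text, "XStringSet"))
    text <- as.character(text)
  if (!is.character(text) || length(text) != 1L || is.na(text))
    stop("'text' must be a single character string")
  if (nchar(text) == 0L)
    stop("'text' must be non-empty")
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  code <- match(chars, c("A", "C", "G", "T", "a", "c", "g", "t"))
  if (anyNA(code)) {
    bad <- which(is.na(code))[1L]
    stop(sprintf("non-ACGT character '%s' at position %d", chars[bad], bad))
  }
  as.integer((code - 1L) %% 4L)
}

# Accept either a raw string/DNAString or an already-encoded integer vector.
.asEncoded <- function(x, what = "sequence") {
  if (is.integer(x) || is.double(x)) {
    x <- as.integer(x)
    if (length(x) == 0L) stop(sprintf("empty %s", what))
    if (any(x < 0L | x > 3L)) stop(sprintf("%s codes must be in 0..3", what))
    return(x)
  }
  encodeSequence(x)
}

.decodeSequence <- function(code) {
  paste(c("A", "C", "G", "T")[code + 1L], collapse = "")
}
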