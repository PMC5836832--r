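#' @include AllClasses.R encode.R
NULL

#' Read and validate a FASTA file of ACGT sequences
#'
#' Thin wrapper over \code{Biostrings::readDNAStringSet} that enforces the
#' package's sequence domain: every record must be non-empty and contain
#' only A, C, G, T (case-insensitive; ambiguity codes are rejected, naming
#' the record and the first offending position).
#'
#' @param path FASTA file path; CRLF line endings and lowercase bases are
#'   accepted.
#' @return a \code{Biostrings::DNAStringSet}.
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readDNAStringSet(path)
  if (!length(set)) stop("no FASTA records in ", path)
  for (k in seq_along(set)) {
    s <- as.character(set[[k]])
    if (nchar(s) == 0L)
      stop(sprintf("record '%s' in %s is empty", names(set)[k], path))
    bad <- regexpr("[^ACGTacgt]", s)
    if (bad != -1L)
      stop(sprintf(
        "record '%s' in %s: non-ACGT character '%s' at position %d",
        names(set)[k], path, substr(s, bad, bad), bad))
  }
  set
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector or \code{DNAStringSet}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeFasta <- function(seqs, path) {
  if (!methods::is(seqs, "XStringSet")) {
    nm <- names(seqs)
    seqs <- Biostrings::DNAStringSet(unname(seqs))
    names(seqs) <- if (is.null(nm)) sprintf("seq%d", seq_along(seqs)) else nm
  }
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Align paired FASTA files record by record
#'
#' Aligns record k of \code{aFile} against record k of \code{bFile} with
#' the chosen engine and returns one report row per pair: ids, score, end
#' coordinates (0-based), CIGAR, and a fill/trace/conversion timing
#' breakdown in seconds (timings are informational; no performance claims
#' attach to them).
#'
#' @param aFile,bFile FASTA paths with equally many records.
#' @param scheme a [ScoringScheme-class].
#' @param engine one of "reference", "naive", "offset", "banded".
#' @param config a [BandConfig-class] (banded engine).
#' @return data.frame.
#' @export
alignPairs <- function(aFile, bFile, scheme = scoringScheme(),
                       engine = c("reference", "naive", "offset", "banded"),
                       config = bandConfig()) {
  engine <- match.arg(engine)
  aSet <- readFasta(aFile); bSet <- readFasta(bFile)
  if (length(aSet) != length(bSet))
    stop("paired FASTA files must have equally many records")
  rows <- vector("list", length(aSet))
  for (k in seq_along(aSet)) {
    a <- encodeSequence(as.character(aSet[[k]]))
    b <- encodeSequence(as.character(bSet[[k]]))
    t0 <- proc.time()[["elapsed"]]
    if (engine == "banded") {
      res <- bandFill(a, b, scheme, config, keepFlags = TRUE)
      t1 <- proc.time()[["elapsed"]]
      path <- tracebackBanded(res)
      score <- res@maxScore; end <- res@maxCell
    } else {
      dp <- switch(engine,
        reference = fillReference(a, b, scheme),
        naive = reconstructAbsolute(fillDiffNaive(a, b, scheme)),
        offset = reconstructAbsolute(toNaive(fillDiffOffset(a, b, scheme))))
      t1 <- proc.time()[["elapsed"]]
      path <- tracebackReference(dp)
      score <- dp@maxScore; end <- dp@maxCell
    }
    t2 <- proc.time()[["elapsed"]]
    cg <- pathToCigar(path)
    t3 <- proc.time()[["elapsed"]]
    rows[[k]] <- data.frame(
      aId = sub(" .*", "", names(aSet)[k]),
      bId = sub(" .*", "", names(bSet)[k]),
      score = score, endI = end[1L], endJ = end[2L],
      cigar = cigarString(cg),
      fillSec = t1 - t0, traceSec = t2 - t1, convSec = t3 - t2)
  }
  do.call(rbind, rows)
}
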