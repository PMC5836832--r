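#' @include AllClasses.R AllGenerics.R path.R
NULL

.newCigar <- function(ops, lengths) {
  # merge adjacent equal ops defensively, then validate
  if (length(ops) > 1L) {
    keep <- c(TRUE, ops[-1L] != ops[-length(ops)])
    grp <- cumsum(keep)
    lengths <- as.integer(rowsum(as.numeric(lengths), grp))
    ops <- ops[keep]
  }
  methods::new("Cigar", ops = as.character(ops), lengths = as.integer(lengths))
}

#' @describeIn cigarString SAM CIGAR string of a Cigar object.
#' @export
setMethod("cigarString", "Cigar", function(x) {
  if (!length(x@ops)) return("")
  paste0(x@lengths, x@ops, collapse = "")
})

setMethod("show", "Cigar", function(object) {
  cat(sprintf("Cigar: %s\n",
              if (length(object@ops)) cigarString(object) else "<empty>"))
  invisible(object)
})

#' Parse a SAM-grammar CIGAR string
#'
#' Only the M/I/D operations this package emits are accepted.
#'
#' @param text character(1) like "12M1D30M" (empty string gives an empty
#'   CIGAR).
#' @return a [Cigar-class].
#' @export
parseCigar <- function(text) {
  if (!is.character(text) || length(text) != 1L)
    stop("'text' must be a single string")
  if (nchar(text) == 0L)
    return(methods::new("Cigar", ops = character(), lengths = integer()))
  m <- gregexpr("[0-9]+[MID]", text)[[1L]]
  toks <- regmatches(text, gregexpr("[0-9]+[MID]", text))[[1L]]
  if (sum(nchar(toks)) != nchar(text) || m[1L] == -1L)
    stop("malformed CIGAR string: ", text)
  lens <- as.integer(sub("[MID]$", "", toks))
  ops <- sub("^[0-9]+", "", toks)
  .newCigar(ops, lens)
}

#' Consumed sequence lengths of a CIGAR
#'
#' @param cg a [Cigar-class].
#' @return integer(2): bases of a consumed (M + D) and bases of b consumed
#'   (M + I).
#' @export
cigarConsumed <- function(cg) {
  c(a = sum(cg@lengths[cg@ops %in% c("M", "D")]),
    b = sum(cg@lengths[cg@ops %in% c("M", "I")]))
}

#' Score a CIGAR against its sequences
#'
#' M runs are scored base by base from the substitution table (matches and
#' mismatches both map to M); I and D runs cost one gap open plus
#' length-many gap extensions in the vertical and horizontal orientation
#' respectively.
#'
#' @param cg a [Cigar-class].
#' @param a,b sequences (strings or encoded).
#' @param scheme a [ScoringScheme-class].
#' @return numeric(1) score.
#' @export
scoreCigar <- function(cg, a, b, scheme = scoringScheme()) {
  a <- .asEncoded(a, "sequence a"); b <- .asEncoded(b, "sequence b")
  tab <- subTable(scheme)
  i <- 0L; j <- 0L; score <- 0
  for (r in seq_along(cg@ops)) {
    k <- cg@lengths[r]
    switch(cg@ops[r],
      M = {
        score <- score +
          sum(tab[4L * a[i + seq_len(k)] + b[j + seq_len(k)] + 1L])
        i <- i + k; j <- j + k
      },
      D = {
        score <- score - scheme@GoH - k * scheme@GeH
        i <- i + k
      },
      I = {
        score <- score - scheme@GoV - k * scheme@GeV
        j <- j + k
      })
  }
  score
}

# ---- path -> CIGAR -------------------------------------------------------

# The path bits are packed little-endian into 30-bit words (bit t of word w
# is path symbol w*30 + t); 30 bits keep every word a positive R integer
# while still letting runs be counted word-at-a-time.
.WORDBITS <- 30L

.packPath <- function(bits) {
  n <- length(bits)
  if (!n) return(integer())
  idx <- (seq_len(n) - 1L) %/% .WORDBITS
  t <- (seq_len(n) - 1L) %% .WORDBITS
  as.integer(rowsum(bits * 2^t, idx))
}

.tzc30 <- function(v) {
  # trailing zero count of a nonzero 30-bit value
  tz <- 0L
  while (v %% 2L == 0L) { v <- v %/% 2L; tz <- tz + 1L }
  tz
}

# Count the zero run starting at 1-based global position pos over n valid
# bits of packed words (word-at-a-time; the software analogue of the
# trailing-zero-count instruction).
.zeroRun <- function(words, n, pos) {
  total <- 0L
  w <- (pos - 1L) %/% .WORDBITS + 1L
  t <- (pos - 1L) %% .WORDBITS
  while (w <= length(words)) {
    v <- words[w] %/% 2L^t
    avail <- .WORDBITS - t
    if (v == 0L) {
      total <- total + avail
      w <- w + 1L; t <- 0L
    } else {
      total <- total + min(.tzc30(v), avail)
      break
    }
  }
  min(total, n - pos + 1L)
}

# Alternating 10101... masks over 30 bits; 1s at even / odd bit offsets.
.ALT_EVEN <- as.integer((4^15 - 1) / 3)
.ALT_ODD <- as.integer(2 * (4^15 - 1) / 3)

#' Convert a bit-encoded path to a CIGAR (bit-counting conversion)
#'
#' Works on the packed word representation: a contiguous horizontal run is
#' a block of zeros measured with a trailing-zero count; a diagonal
#' ("10"-repeat) run is reduced to a zero run by XORing with the
#' alternating 1010... mask of matching phase; vertical runs are counted as
#' ones.  Horizontal transitions map to D (a is the reference), vertical
#' to I, diagonal to M.  [pathToCigarNaive()] is the symbol-by-symbol
#' oracle for this converter.
#'
#' @param path a [PathString-class].
#' @return a [Cigar-class].
#' @examples
#' cigarString(pathToCigar(pathString("10101010")))  # "4M"
#' @export
pathToCigar <- function(path) {
  bits <- path@bits
  n <- length(bits)
  if (!n) return(methods::new("Cigar", ops = character(), lengths = integer()))
  words <- .packPath(bits)
  bitAt <- function(pos)
    (words[(pos - 1L) %/% .WORDBITS + 1L] %/%
       2L^((pos - 1L) %% .WORDBITS)) %% 2L
  ops <- character(); lens <- integer()
  pos <- 1L
  while (pos <= n) {
    if (bitAt(pos) == 0L) {
      l <- .zeroRun(words, n, pos)
      ops <- c(ops, "D"); lens <- c(lens, l)
      pos <- pos + l
    } else if (pos < n && bitAt(pos + 1L) == 0L) {
      mask <- if ((pos - 1L) %% 2L == 0L) .ALT_EVEN else .ALT_ODD
      xw <- bitwXor(words, rep(mask, length(words)))
      l <- .zeroRun(xw, n, pos)
      m <- l %/% 2L
      ops <- c(ops, "M"); lens <- c(lens, m)
      pos <- pos + 2L * m
    } else {
      # ones run: XOR with all-ones reduces it to a zero run
      xw <- bitwXor(words, rep(as.integer(2^.WORDBITS - 1), length(words)))
      l <- .zeroRun(xw, n, pos)
      if (pos + l <= n && bitAt(pos + l) == 0L) {
        # the last 1 pairs with the following 0 as a diagonal
        l <- l - 1L
      }
      ops <- c(ops, "I"); lens <- c(lens, l)
      pos <- pos + l
    }
  }
  .newCigar(ops, lens)
}

#' Convert a path to a CIGAR symbol by symbol
#'
#' Decodes the path into transitions and run-length encodes them; the
#' straightforward oracle for the bit-counting converter [pathToCigar()].
#'
#' @param path a [PathString-class].
#' @return a [Cigar-class].
#' @export
pathToCigarNaive <- function(path) {
  tok <- decodePath(path, "L2R")
  if (!length(tok))
    return(methods::new("Cigar", ops = character(), lengths = integer()))
  runs <- rle(unname(c(V = "I", H = "D", D = "M")[match(tok, c("V", "H", "D"))]))
  .newCigar(runs$values, runs$lengths)
}
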