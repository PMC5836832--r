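#' @include AllClasses.R AllGenerics.R
NULL

# Build a PathString from transitions collected in traceback order
# (end -> origin); codes 1 = vertical, 2 = horizontal, 3 = diagonal.
# The alignment-order encoding is "1" vertical, "0" horizontal, "10"
# diagonal, concatenated.
.pathFromTraceback <- function(trans) {
  al <- rev(trans)
  if (!length(al)) return(methods::new("PathString", bits = integer()))
  lens <- ifelse(al == 3L, 2L, 1L)
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  bits <- integer(ends[length(ends)])
  bits[starts[al == 1L]] <- 1L
  bits[starts[al == 3L]] <- 1L   # diagonal = "1" then "0"
  methods::new("PathString", bits = bits)
}

#' Path from an ASCII 0/1 string
#'
#' @param chars a single string of 0/1 characters (alignment order).
#' @return a [PathString-class].
#' @export
pathString <- function(chars) {
  if (!is.character(chars) || length(chars) != 1L)
    stop("'chars' must be a single 0/1 string")
  if (nchar(chars) == 0L)
    return(methods::new("PathString", bits = integer()))
  bits <- as.integer(strsplit(chars, "", fixed = TRUE)[[1L]])
  if (anyNA(bits) || !all(bits %in% 0:1))
    stop("malformed path: characters must be 0 or 1")
  methods::new("PathString", bits = bits)
}

#' Render a path as an ASCII 0/1 string
#'
#' @param path a [PathString-class].
#' @return character(1).
#' @export
pathChars <- function(path) paste(path@bits, collapse = "")

#' @describeIn pathChars bit vector accessor.
#' @export
setMethod("pathBits", "PathString", function(x) x@bits)

setMethod("show", "PathString", function(object) {
  n <- length(object@bits)
  s <- pathChars(object)
  if (n > 60L) s <- paste0(substr(s, 1L, 57L), "...")
  cat(sprintf("PathString of %d bits: %s\n", n, s))
  invisible(object)
})

#' Decode a bit-encoded path into its transition list
#'
#' The encoding ("1" vertical, "0" horizontal, "10" diagonal) is uniquely
#' decodable in both reading directions for any path produced under the
#' traceback priority vertical > horizontal > diagonal, because such paths
#' never contain a vertical transition immediately followed by a horizontal
#' one (the equal-scoring horizontal-then-vertical order always exists and
#' the priority selects it).  Reading left to right, a "1" followed by a
#' "0" is therefore always a diagonal.
#'
#' @param path a [PathString-class].
#' @param direction "L2R" or "R2L" reading direction; both must give the
#'   same transition list for a valid path.
#' @return character vector over {"V","H","D"} in alignment order
#'   (D = diagonal).
#' @examples
#' decodePath(pathString("1001010"))  # D H D D
#' @export
decodePath <- function(path, direction = c("L2R", "R2L")) {
  direction <- match.arg(direction)
  bits <- path@bits
  n <- length(bits)
  if (!n) return(character())
  out <- character(n)
  k <- 0L
  if (direction == "L2R") {
    pos <- 1L
    while (pos <= n) {
      k <- k + 1L
      if (bits[pos] == 0L) {
        out[k] <- "H"; pos <- pos + 1L
      } else if (pos < n && bits[pos + 1L] == 0L) {
        out[k] <- "D"; pos <- pos + 2L
      } else {
        out[k] <- "V"; pos <- pos + 1L
      }
    }
    out[seq_len(k)]
  } else {
    pos <- n
    while (pos >= 1L) {
      k <- k + 1L
      if (bits[pos] == 1L) {
        out[k] <- "V"; pos <- pos - 1L
      } else if (pos > 1L && bits[pos - 1L] == 1L) {
        out[k] <- "D"; pos <- pos - 2L
      } else {
        out[k] <- "H"; pos <- pos - 1L
      }
    }
    rev(out[seq_len(k)])
  }
}

#' Path length identity
#'
#' The number of bits of an alignment path equals the number of consumed
#' bases of a plus the number of consumed bases of b: every horizontal or
#' vertical transition contributes one bit and consumes one base, every
#' diagonal contributes two bits and consumes one base of each.
#'
#' @param path a [PathString-class].
#' @param aConsumed,bConsumed integer base counts.
#' @return logical(1).
#' @export
pathLengthIdentity <- function(path, aConsumed, bConsumed) {
  length(path@bits) == aConsumed + bConsumed
}

#' Replay a path against its sequences
#'
#' Walks the decoded path from the origin, summing substitution scores on
#' diagonal transitions and affine gap costs (open + length * extension,
#' separately per gap run and orientation) on gap runs.  Replaying a path
#' emitted by any of the engines must reproduce the engine's reported
#' score exactly.
#'
#' @param path a [PathString-class].
#' @param a,b sequences (strings or encoded).
#' @param scheme a [ScoringScheme-class].
#' @return list with \code{score}, \code{aConsumed}, \code{bConsumed}.
#' @export
replayPath <- function(path, a, b, scheme = scoringScheme()) {
  a <- .asEncoded(a, "sequence a")
  b <- .asEncoded(b, "sequence b")
  tok <- decodePath(path, "L2R")
  if (!length(tok))
    return(list(score = 0, aConsumed = 0L, bConsumed = 0L))
  tab <- subTable(scheme)
  runs <- rle(tok)
  score <- 0
  i <- 0L; j <- 0L
  for (r in seq_along(runs$lengths)) {
    k <- runs$lengths[r]
    op <- runs$values[r]
    if (op == "D") {
      ii <- i + seq_len(k); jj <- j + seq_len(k)
      if (max(ii) > length(a) || max(jj) > length(b))
        stop("path overruns its sequences")
      score <- score + sum(tab[4L * a[ii] + b[jj] + 1L])
      i <- i + k; j <- j + k
    } else if (op == "H") {
      score <- score - scheme@GoH - k * scheme@GeH
      i <- i + k
      if (i > length(a)) stop("path overruns sequence a")
    } else {
      score <- score - scheme@GoV - k * scheme@GeV
      j <- j + k
      if (j > length(b)) stop("path overruns sequence b")
    }
  }
  list(score = score, aConsumed = i, bConsumed = j)
}
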