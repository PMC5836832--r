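#' @include AllClasses.R cigar.R encode.R
NULL

#' Mutation profile for synthetic read pairs
#'
#' Per-base event probabilities used by [generatePair()].  The defaults are
#' the error profile of filtered nanopore read-pair data: mismatch 0.061,
#' insertion 0.014, deletion 0.091, with contiguous gaps capped at 20 bp
#' (pairs with longer gaps being excluded from banded-alignment
#' benchmarks because a 32-lane band may lose them).
#'
#' @slot mismatchRate,insertionRate,deletionRate numeric(1) per-base
#'   probabilities; non-negative with sum < 1.
#' @slot maxGap numeric(1) cap on contiguous gap length (Inf for none).
#' @slot length integer(1) reference sequence length (>= 1).
#' @slot seed integer(1) RNG seed; generation is deterministic given the
#'   profile.
#' @exportClass MutationProfile
setClass("MutationProfile",
  representation(mismatchRate = "numeric", insertionRate = "numeric",
                 deletionRate = "numeric", maxGap = "numeric",
                 length = "integer", seed = "integer"))

setValidity("MutationProfile", function(object) {
  msg <- character()
  r <- c(object@mismatchRate, object@insertionRate, object@deletionRate)
  if (any(r < 0)) msg <- c(msg, "rates must be non-negative")
  if (sum(r) >= 1) msg <- c(msg, "rates must sum to less than 1")
  if (object@length < 1L) msg <- c(msg, "length must be >= 1")
  if (object@maxGap < 1) msg <- c(msg, "maxGap must be >= 1 (or Inf)")
  if (length(msg)) msg else TRUE
})

#' @rdname MutationProfile-class
#' @param mismatchRate,insertionRate,deletionRate,maxGap,length,seed see
#'   slots.
#' @return a validated \code{MutationProfile}.
#' @export
mutationProfile <- function(mismatchRate = 0.061, insertionRate = 0.014,
                            deletionRate = 0.091, maxGap = 20,
                            length = 25000L, seed = 1L) {
  methods::new("MutationProfile",
               mismatchRate = as.numeric(mismatchRate),
               insertionRate = as.numeric(insertionRate),
               deletionRate = as.numeric(deletionRate),
               maxGap = as.numeric(maxGap), length = as.integer(length),
               seed = as.integer(seed))
}

setMethod("show", "MutationProfile", function(object) {
  cat(sprintf(
    "MutationProfile: length %d, mismatch %.3f, ins %.3f, del %.3f, maxGap %g, seed %d\n",
    object@length, object@mismatchRate, object@insertionRate,
    object@deletionRate, object@maxGap, object@seed))
  invisible(object)
})

# run the expression with a private RNG stream seeded from `seed`,
# restoring the caller's RNG state afterwards
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a mutated read pair with its true alignment
#'
#' Draws a uniform random ACGT reference a of the profile's length, then
#' derives b by walking a once: before each position an insertion run may
#' open (probability \code{insertionRate}), and the position itself is
#' deleted (probability \code{deletionRate}), substituted (probability
#' \code{mismatchRate}) or copied.  Gap run lengths are geometric -- a run
#' extends with the same per-base probability that opened it -- truncated
#' at \code{maxGap} (and, for deletions, at the end of a).  The CIGAR of
#' the generating walk is returned as ground truth; its I runs consume
#' only b, D runs only a, and replaying it against (a, b) consumes both
#' sequences exactly.
#'
#' @param profile a [MutationProfile-class].
#' @return list with \code{a}, \code{b} (character), \code{cigar} (the true
#'   [Cigar-class]), and \code{events}, a named count vector of mismatch,
#'   insertion and deletion run starts.
#' @export
generatePair <- function(profile) {
  methods::validObject(profile)
  pI <- profile@insertionRate; pD <- profile@deletionRate
  pM <- profile@mismatchRate
  n <- profile@length
  .withSeed(profile@seed, {
    a <- sample(0:3, n, replace = TRUE)
    ops <- character(2L * n + 2L); opLen <- integer(2L * n + 2L); no <- 0L
    bbuf <- integer(n + as.integer(2 * pI * n) + 64L); nb <- 0L
    push <- function(op, k) {
      if (no > 0L && ops[no] == op) opLen[no] <<- opLen[no] + k
      else { no <<- no + 1L; ops[no] <<- op; opLen[no] <<- k }
    }
    nMis <- 0L; nIns <- 0L; nDel <- 0L
    i <- 1L
    while (i <= n) {
      if (pI > 0 && stats::runif(1L) < pI) {
        k <- min(1L + stats::rgeom(1L, 1 - pI), profile@maxGap)
        ins <- sample(0:3, k, replace = TRUE)
        if (nb + k > length(bbuf)) bbuf <- c(bbuf, integer(n))
        bbuf[nb + seq_len(k)] <- ins; nb <- nb + k
        push("I", k)
        nIns <- nIns + 1L
      }
      u <- stats::runif(1L)
      if (u < pD) {
        k <- min(1L + stats::rgeom(1L, 1 - pD), profile@maxGap, n - i + 1L)
        push("D", k)
        i <- i + k
        nDel <- nDel + 1L
      } else {
        nb <- nb + 1L
        if (nb > length(bbuf)) bbuf <- c(bbuf, integer(n))
        if (u < pD + pM) {
          bbuf[nb] <- (a[i] + sample(1:3, 1L)) %% 4L
          nMis <- nMis + 1L
        } else {
          bbuf[nb] <- a[i]
        }
        push("M", 1L)
        i <- i + 1L
      }
    }
    if (nb == 0L) {
      # degenerate draw (every base deleted): convert the final deleted
      # base into a copied one so the pair stays alignable
      bbuf[1L] <- a[n]; nb <- 1L
      opLen[no] <- opLen[no] - 1L           # last op is necessarily a D run
      if (opLen[no] == 0L) no <- no - 1L
      push("M", 1L)
    }
    list(a = .decodeSequence(a), b = .decodeSequence(bbuf[seq_len(nb)]),
         cigar = .newCigar(ops[seq_len(no)], opLen[seq_len(no)]),
         events = c(mismatch = nMis, insertion = nIns, deletion = nDel))
  })
}

#' Generate a reproducible set of read pairs as paired FASTA
#'
#' Writes n pairs (pair i generated with seed \code{baseSeed + i - 1}) to
#' two FASTA files plus a tab-separated truth table carrying the seed, the
#' true CIGAR and the event counts of every pair.  Byte-identical output
#' for identical arguments.
#'
#' @param profile a [MutationProfile-class] (its seed slot is ignored in
#'   favour of the derived per-pair seeds).
#' @param n number of pairs (>= 1).
#' @param baseSeed integer base seed.
#' @param aFile,bFile,truthFile output paths.
#' @return invisibly, the truth data.frame.
#' @export
pairSet <- function(profile, n, baseSeed = profile@seed,
                    aFile = "pairs_a.fasta", bFile = "pairs_b.fasta",
                    truthFile = "pairs_truth.tsv") {
  stopifnot(n >= 1L)
  aSeq <- character(n); bSeq <- character(n)
  truth <- vector("list", n)
  for (k in seq_len(n)) {
    pr <- profile
    pr@seed <- as.integer(baseSeed + k - 1L)
    g <- generatePair(pr)
    aSeq[k] <- g$a; bSeq[k] <- g$b
    truth[[k]] <- data.frame(
      pair = sprintf("pair%04d", k), seed = pr@seed,
      cigar = cigarString(g$cigar),
      mismatches = g$events[["mismatch"]],
      insertions = g$events[["insertion"]],
      deletions = g$events[["deletion"]])
  }
  truth <- do.call(rbind, truth)
  hdr <- sprintf("%s seed=%d cigar=%s", truth$pair, truth$seed, truth$cigar)
  aSet <- Biostrings::DNAStringSet(aSeq); names(aSet) <- hdr
  bSet <- Biostrings::DNAStringSet(bSeq); names(bSet) <- hdr
  Biostrings::writeXStringSet(aSet, aFile)
  Biostrings::writeXStringSet(bSet, bFile)
  utils::write.table(truth, truthFile, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(truth)
}
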