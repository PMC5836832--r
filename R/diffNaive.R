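#' @include AllClasses.R reference.R
NULL

#' Fill the naive difference matrices
#'
#' Computes the four difference matrices of the semi-global DP -- the
#' horizontal and vertical neighbour differences dH, dV of S and the
#' gap-matrix offsets dE = E - S, dF = F - S -- together with the diagonal
#' intermediate A = S[i,j] - S[i-1,j-1], using only the difference
#' recurrences:
#' \deqn{A = \max(s,\; dE[i-1,j] + dV[i-1,j] - GeH,\;
#'                dF[i,j-1] + dH[i,j-1] - GeV)}
#' \deqn{dH = A - dV[i-1,j], \quad dV = A - dH[i,j-1]}
#' \deqn{dE = \max(-GoH,\; dE[i-1,j] - dH - GeH), \quad
#'       dF = \max(-GoV,\; dF[i,j-1] - dV - GeV)}
#' The matrix is filled antidiagonal by antidiagonal.  Edge rows/columns
#' carry the initial conditions of the difference form: dH is -(GoH+GeH) at
#' (1,0) and -GeH further down the j = 0 row, dV symmetrically on the
#' i = 0 column, dE is 0 on its j = 0 row and clipped to -GoH on the i = 0
#' column (replacing the -inf of the nondifference form), dF symmetrically.
#'
#' Every value is bounded: dH in [-GoH-GeH, M+GoV+GeV], dV in
#' [-GoV-GeV, M+GoH+GeH], dE in [-GoH, 0], dF in [-GoV, 0]
#' (see [checkNaiveBounds()]), which is what makes narrow integer storage
#' possible.
#'
#' @inheritParams fillReference
#' @return a [NaiveDiffState-class].
#' @seealso [reconstructAbsolute()] for exact recovery of S, E, F.
#' @export
fillDiffNaive <- function(a, b, scheme = scoringScheme()) {
  methods::validObject(scheme)
  a <- .asEncoded(a, "sequence a")
  b <- .asEncoded(b, "sequence b")
  la <- length(a); lb <- length(b)
  GoH <- scheme@GoH; GeH <- scheme@GeH; GoV <- scheme@GoV; GeV <- scheme@GeV
  nr <- la + 1L
  dH <- matrix(NA_real_, nr, lb + 1L)
  dV <- matrix(NA_real_, nr, lb + 1L)
  dE <- matrix(NA_real_, nr, lb + 1L)
  dF <- matrix(NA_real_, nr, lb + 1L)
  A <- matrix(NA_real_, nr, lb + 1L)
  # initial conditions
  dH[-1L, 1L] <- c(-(GoH + GeH), rep(-GeH, la - 1L))
  dV[1L, -1L] <- c(-(GoV + GeV), rep(-GeV, lb - 1L))
  dE[, 1L] <- 0
  dE[1L, -1L] <- -GoH
  dF[1L, ] <- 0
  dF[-1L, 1L] <- -GoV
  tab <- subTable(scheme)
  for (p in 2:(la + lb)) {
    ii <- max(1L, p - lb):min(la, p - 1L)
    jj <- p - ii
    linC <- ii + 1L + jj * nr
    linL <- ii + jj * nr            # (i-1, j)
    linU <- ii + 1L + (jj - 1L) * nr  # (i, j-1)
    sv <- tab[4L * a[ii] + b[jj] + 1L]
    Av <- pmax(sv, dE[linL] + dV[linL] - GeH, dF[linU] + dH[linU] - GeV)
    dHv <- Av - dV[linL]
    dVv <- Av - dH[linU]
    A[linC] <- Av
    dH[linC] <- dHv
    dV[linC] <- dVv
    dE[linC] <- pmax(-GoH, dE[linL] - dHv - GeH)
    dF[linC] <- pmax(-GoV, dF[linU] - dVv - GeV)
  }
  methods::new("NaiveDiffState", a = a, b = b, scheme = scheme,
               dH = dH, dV = dV, dE = dE, dF = dF, A = A)
}

#' Reconstruct absolute DP matrices from differences
#'
#' The difference matrices plus the single absolute value S[0,0] = 0
#' determine S exactly by telescoping; the result must not depend on the
#' summation order, so the row-first and column-first reconstructions are
#' both computed and compared cellwise (a mismatch means the state violates
#' the path-independence identity dH[i,j] + dV[i-1,j] = dV[i,j] + dH[i,j-1]
#' and is reported as corruption).  E and F follow as S + dE and S + dF;
#' their unreachable edges inherit the clipped values -GoH and -GoV
#' relative to S.
#'
#' @param st a [NaiveDiffState-class].
#' @return a [FullDP-class] (with clipped E/F edges; interior cells and S
#'   agree exactly with [fillReference()]).
#' @export
reconstructAbsolute <- function(st) {
  la <- length(st@a); lb <- length(st@b)
  nr <- la + 1L
  # row-first: column j = 0 by dH, then right by dV
  S1 <- matrix(NA_real_, nr, lb + 1L)
  S1[, 1L] <- c(0, cumsum(st@dH[-1L, 1L]))
  for (j in seq_len(lb)) S1[, j + 1L] <- S1[, j] + st@dV[, j + 1L]
  # column-first: row i = 0 by dV, then down by dH
  S2 <- matrix(NA_real_, nr, lb + 1L)
  S2[1L, ] <- c(0, cumsum(st@dV[1L, -1L]))
  for (i in seq_len(la)) S2[i + 1L, ] <- S2[i, ] + st@dH[i + 1L, ]
  if (!isTRUE(all.equal(S1, S2, tolerance = 0)))
    stop("corrupt difference state: reconstruction is order-dependent ",
         "(path-independence violated)")
  E <- S1 + st@dE
  F <- S1 + st@dF
  mc <- .argmaxCell(S1, nr)
  methods::new("FullDP", a = st@a, b = st@b, scheme = st@scheme,
               S = S1, E = E, F = F,
               maxScore = S1[mc[1L] + 1L, mc[2L] + 1L], maxCell = mc,
               neg = .negSentinel(la, lb, st@scheme))
}

#' Check the naive difference bounds
#'
#' Reports the observed extrema of each difference matrix against its
#' analytic bounds:
#' -GoH-GeH <= dH <= M+GoV+GeV, -GoV-GeV <= dV <= M+GoH+GeH,
#' -GoH <= dE <= 0, -GoV <= dF <= 0.
#'
#' @param st a [NaiveDiffState-class].
#' @param scheme the scheme to check against (defaults to the state's own).
#' @return a list with \code{report}, a data.frame of one row per matrix
#'   (observed min/max, bound lower/upper, pass), and \code{pass},
#'   logical(1).
#' @export
checkNaiveBounds <- function(st, scheme = st@scheme) {
  M <- maxSub(scheme)
  GoH <- scheme@GoH; GeH <- scheme@GeH; GoV <- scheme@GoV; GeV <- scheme@GeV
  bounds <- rbind(
    dH = c(-GoH - GeH, M + GoV + GeV),
    dV = c(-GoV - GeV, M + GoH + GeH),
    dE = c(-GoH, 0),
    dF = c(-GoV, 0))
  obs <- t(vapply(list(st@dH, st@dV, st@dE, st@dF),
                  function(m) range(m, na.rm = TRUE), numeric(2L)))
  report <- data.frame(
    matrix = rownames(bounds),
    observedMin = obs[, 1L], observedMax = obs[, 2L],
    lower = bounds[, 1L], upper = bounds[, 2L],
    pass = obs[, 1L] >= bounds[, 1L] & obs[, 2L] <= bounds[, 2L],
    row.names = NULL)
  list(report = report, pass = all(report$pass))
}

#' Minimal signed bit width for the naive difference values
#'
#' The smallest two's-complement width w such that every endpoint of the
#' four bounding intervals (and hence every representable difference value)
#' lies in [-2^(w-1), 2^(w-1) - 1].  For the scheme M = 2, gap open 4, gap
#' extension 1 this is 4 bits.
#'
#' @param scheme a [ScoringScheme-class].
#' @return integer(1) bit width.
#' @examples
#' minSignedBits(scoringScheme(match = 2, mismatch = -2,
#'                             gapOpen = 4, gapExtend = 1))  # 4
#' @export
minSignedBits <- function(scheme) {
  M <- maxSub(scheme)
  GoH <- scheme@GoH; GeH <- scheme@GeH; GoV <- scheme@GoV; GeV <- scheme@GeV
  endpoints <- c(-GoH - GeH, M + GoV + GeV,
                 -GoV - GeV, M + GoH + GeH,
                 -GoH, 0, -GoV, 0)
  for (w in 1:62) {
    if (min(endpoints) >= -2^(w - 1) && max(endpoints) <= 2^(w - 1) - 1)
      return(w)
  }
  stop("bound endpoints exceed 62-bit range")   # unreachable for valid schemes
}

setMethod("show", "NaiveDiffState", function(object) {
  cat(sprintf("NaiveDiffState: |a| = %d, |b| = %d (dH, dV, dE, dF, A)\n",
              length(object@a), length(object@b)))
  invisible(object)
})
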