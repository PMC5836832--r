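#' @include AllClasses.R diffNaive.R diffOffset.R criticalPath.R
NULL

#' Analytic diagnostics for a scheme and band configuration
#'
#' Collects the analytic constants of the difference formulations for a
#' given scoring scheme: the minimal signed bit width covering the naive
#' difference bounds, the offset-form upper bound M + GoH + GeH + GoV +
#' GeV, the per-cell critical path lengths of the three formulations from
#' the dependency-DAG analyzer, and the cells-per-block count of the
#' banded engine (W lanes times 32 vectors).
#'
#' @param scheme a [ScoringScheme-class].
#' @param config a [BandConfig-class].
#' @return named list.
#' @examples
#' diagnosticsReport(scoringScheme())$criticalPath  # offset 4, naive 8, nondiff 5
#' @export
diagnosticsReport <- function(scheme = scoringScheme(),
                              config = bandConfig()) {
  list(
    minSignedBits = minSignedBits(scheme),
    offsetBound = offsetBound(scheme),
    criticalPath = c(offset_diff = criticalPathLength("offset_diff"),
                     naive_diff = criticalPathLength("naive_diff"),
                     nondiff = criticalPathLength("nondiff")),
    cellsPerBlock = as.integer(config@W) * config@blockLen,
    scheme = sprintf(
      "M=%g GoH=%g GeH=%g GoV=%g GeV=%g", maxSub(scheme),
      scheme@GoH, scheme@GeH, scheme@GoV, scheme@GeV))
}
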