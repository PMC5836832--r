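#' @include AllClasses.R
NULL

# Symbolic per-cell dependency DAG.  Leaves are quantities available before
# the cell update: values from previously computed cells, sequence bases,
# precomputed tables (including sG) and scheme constants.  Every internal
# node is one basic binary operation (add, sub, or two-operand max); an
# n-ary max is decomposed into a balanced tree of binary maxes.  Node depth
# is the operation count of its longest dependency chain.
.dagBuilder <- function() {
  env <- new.env(parent = emptyenv())
  env$nOps <- 0L
  leaf <- function(label) list(label = label, depth = 0L)
  bop <- function(op, x, y) {
    env$nOps <- env$nOps + 1L
    list(label = op, depth = 1L + max(x$depth, y$depth))
  }
  maxn <- function(args) {
    if (length(args) == 1L) return(args[[1L]])
    h <- length(args) %/% 2L
    bop("max", maxn(args[seq_len(h)]), maxn(args[-seq_len(h)]))
  }
  list(leaf = leaf, bop = bop, maxn = maxn, env = env)
}

#' Per-cell dependency DAG of a DP formulation
#'
#' Builds the operand dependency graph of one cell update for the chosen
#' formulation and returns the operation depth of each output the cell must
#' produce, the number of distinct binary operations, and the critical path
#' (the longest chain over all outputs).  Shared subexpressions (for
#' example the E-extension term that feeds both S and E in the
#' nondifference form) are counted once.
#'
#' @param formulation "nondiff" (S/E/F of the classical recurrences),
#'   "naive_diff" (A, dH, dV, dE, dF) or "offset_diff"
#'   (A_G, dH_G, dV_G, dE'_G, dF'_G).
#' @return list with \code{outputs} (named integer depths), \code{nOps},
#'   and \code{criticalPath}.
#' @export
recurrenceDAG <- function(formulation = c("nondiff", "naive_diff",
                                          "offset_diff")) {
  if (length(formulation) != 1L ||
      !formulation %in% c("nondiff", "naive_diff", "offset_diff"))
    stop("unknown formulation: ",
         paste(formulation, collapse = ", "),
         " (use nondiff, naive_diff or offset_diff)")
  d <- .dagBuilder()
  leaf <- d$leaf; bop <- d$bop; maxn <- d$maxn
  outputs <- switch(formulation,
    nondiff = {
      Sdiag <- leaf("S[i-1,j-1]"); Eprev <- leaf("E[i-1,j]")
      Fprev <- leaf("F[i,j-1]"); s <- leaf("s(a,b)")
      geh <- leaf("GeH"); gev <- leaf("GeV")
      goh <- leaf("GoH"); gov <- leaf("GoV")
      eext <- bop("sub", Eprev, geh)
      fext <- bop("sub", Fprev, gev)
      S <- maxn(list(bop("add", Sdiag, s), eext, fext))
      E <- maxn(list(bop("sub", S, goh), eext))
      F <- maxn(list(bop("sub", S, gov), fext))
      list(S = S, E = E, F = F)
    },
    naive_diff = {
      s <- leaf("s(a,b)")
      dEl <- leaf("dE[i-1,j]"); dVl <- leaf("dV[i-1,j]")
      dFu <- leaf("dF[i,j-1]"); dHu <- leaf("dH[i,j-1]")
      geh <- leaf("GeH"); gev <- leaf("GeV")
      goh <- leaf("-GoH"); gov <- leaf("-GoV")
      A <- maxn(list(s,
                     bop("sub", bop("add", dEl, dVl), geh),
                     bop("sub", bop("add", dFu, dHu), gev)))
      dH <- bop("sub", A, dVl)
      dV <- bop("sub", A, dHu)
      dE <- maxn(list(goh, bop("sub", bop("sub", dEl, dH), geh)))
      dF <- maxn(list(gov, bop("sub", bop("sub", dFu, dV), gev)))
      list(A = A, dH = dH, dV = dV, dE = dE, dF = dF)
    },
    offset_diff = {
      sG <- leaf("sG(a,b)")   # precomputed table: a leaf
      dEl <- leaf("dE'G[i-1,j]"); dVl <- leaf("dVG[i-1,j]")
      dFu <- leaf("dF'G[i,j-1]"); dHu <- leaf("dHG[i,j-1]")
      goh <- leaf("GoH"); gov <- leaf("GoV")
      AG <- maxn(list(sG, dEl, dFu))
      dHG <- bop("sub", AG, dVl)
      dVG <- bop("sub", AG, dHu)
      dEG <- bop("sub", maxn(list(AG, bop("add", dEl, goh))), dHu)
      dFG <- bop("sub", maxn(list(AG, bop("add", dFu, gov))), dVl)
      list(AG = AG, dHG = dHG, dVG = dVG, dEG = dEG, dFG = dFG)
    })
  depths <- vapply(outputs, function(o) o$depth, integer(1L))
  list(outputs = depths, nOps = d$env$nOps,
       criticalPath = max(depths))
}

#' Critical path length of a DP formulation
#'
#' Length of the longest chain of dependent basic binary operations in one
#' cell update: 4 for the offset difference recurrences, 8 for the naive
#' difference recurrences, 5 for the nondifference recurrences.  Shorter
#' critical paths leave more instruction-level parallelism to a superscalar
#' processor.
#'
#' @inheritParams recurrenceDAG
#' @return integer(1).
#' @examples
#' criticalPathLength("offset_diff")  # 4
#' criticalPathLength("naive_diff")   # 8
#' criticalPathLength("nondiff")      # 5
#' @export
criticalPathLength <- function(formulation) {
  recurrenceDAG(formulation)$criticalPath
}
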