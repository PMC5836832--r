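---
title: "Semi-global alignment with difference recurrences: model and design"
author: "diffalign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-global alignment with difference recurrences: model and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diffalign)
```

## The model

`diffalign` computes **semi-global** pairwise alignments of nucleotide
sequences under an affine gap penalty: one alignment end is pinned at the
origin of the dynamic-programming (DP) matrix, the other end is free, and
the alignment score is the matrix-wide maximum of the score matrix `S`.
This is the alignment flavour used to extend a seed match between two long
reads: the 5' ends are anchored, the 3' ends are open.

Sequence `a` (length `|a|`) runs horizontally (index `i`), sequence `b`
vertically (index `j`); cell `(i, j)` consumes the half-open prefixes
`a[0..i)` and `b[0..j)`.  With substitution scores `s(x, y)` (maximum `M
>= 0`) and gap penalty magnitudes `GoH, GeH` (horizontal: consuming `a`)
and `GoV, GeV` (vertical), the classical Gotoh recurrences use three
matrices: `S`, plus `E` and `F` carrying the best horizontally- and
vertically-gapped scores.  A gap of length `k` costs `Go + k * Ge`.  Edge
cells are initialised as a gap from the origin, and the `E`/`F` edges that
no alignment can reach are a `-inf` sentinel (represented finitely, low
enough never to win a maximum).  `fillReference()` implements these
recurrences and is the package's ground-truth oracle.

### Difference form

Because the semi-global recurrences never compare against an absolute
constant (unlike local alignment's clamp at 0), they can be rewritten
entirely in terms of *differences* between adjacent cells:

* `dH[i,j] = S[i,j] - S[i-1,j]`, `dV[i,j] = S[i,j] - S[i,j-1]`
* `dE[i,j] = E[i,j] - S[i,j]`, `dF[i,j] = F[i,j] - S[i,j]`

plus the diagonal intermediate `A[i,j] = S[i,j] - S[i-1,j-1]`.  All four
difference matrices are bounded by constants of the scheme --
`-GoH-GeH <= dH <= M+GoV+GeV`, `-GoH <= dE <= 0`, and symmetrically --
so arbitrarily long alignments can be filled in narrow integer arithmetic
(`minSignedBits()` gives the width; 4 bits suffice for `M = 2, Go = 4,
Ge = 1`).  `fillDiffNaive()` implements this form and
`reconstructAbsolute()` recovers `S`, `E`, `F` exactly by telescoping from
the single absolute anchor `S[0,0] = 0`.  Recovery is computed in two
summation orders and compared, so a corrupted state (violating the
path-independence identity `dH[i,j] + dV[i-1,j] = dV[i,j] + dH[i,j-1]`)
is detected rather than silently accepted.

The `-inf` edges of `E` (at `i = 0`) and `F` (at `j = 0`) are *clipped* to
`dE = -GoH` and `dF = -GoV` in difference form.  The clip is exactly
equivalent to the `-inf` convention whenever

```
min s(x, y) > -(GeH + GeV)     (strict)
```

which every practical long-read scheme satisfies (the default unit scheme
has `-1 > -2`).  Below this bound the clipped edge can either admit an
open-gap-after-edge-gap path that the `-inf` convention forbids, or --
more subtly -- seed a spurious gap-*extension* chain in the first
interior row, where `dE[1,j]` takes its extension branch off the clipped
edge whenever `dH[1,j] < -GeH`, a situation the displayed condition rules
out (`dH[1,j] >= min s + GeV`).  At the non-strict boundary `min s =
-(GeH + GeV)` the cell *values* still agree (the competing branches tie)
but traceback paths may diverge, since the clipped edge flags a gap
extension the `-inf` convention cannot take.  The package treats the
strict condition as an assumption of the difference formulations, and the
property-test scheme generator samples inside it.

### Offset form

An affine shift turns all differences non-negative and bounded by the
*single* constant `M + GoH + GeH + GoV + GeV` (`offsetBound()`):

* `dHG = dH + GoH + GeH`, `dVG = dV + GoV + GeV`
* `dE'G = dE + dV + GoH + GoV + GeV`, `dF'G = dF + dH + GoV + GoH + GeH`
* `sG(x,y) = s(x,y) + GoH + GeH + GoV + GeV` (precomputed 16-entry table)

`fillDiffOffset()` implements the shifted recurrences; `toNaive()` is the
exact inverse.  Beyond unsigned storage, the shift shortens the per-cell
critical path: counting basic binary operations (add, sub, two-operand
max; an n-ary max as a balanced tree of binary maxes; previously computed
cells and precomputed tables as leaves), one cell update takes a longest
dependent chain of **4** operations in offset form, versus **8** for the
naive differences and **5** for the nondifference recurrences.
`recurrenceDAG()` builds the operand graph and `criticalPathLength()`
reports the counts; the balanced-binary max convention is what reproduces
these numbers (a left-to-right max chain would count differently, which is
why the convention is part of the analyzer's definition).

### Exact equivalence as the correctness contract

The three formulations are algebraic rewrites of one another, so the
package's central invariant is *exact* equivalence: for any valid scheme
(within the clip condition above) and any sequence pair, the
reconstructed `S` matrices agree cellwise, maxima agree, and -- under the
shared traceback priority -- paths agree.  The test suite sweeps 500
randomized (scheme, pair) instances with lengths 1-300 plus targeted edge
cases; all comparisons are `identical()`, not tolerance-based, since every
quantity is integer-valued.

## The adaptive banded engine

`bandFill()` runs the offset recurrences inside a moving band of `W`
antidiagonal lanes (default 32, matching a 32-wide vector of 8-bit
integers).  Lane `q = 0` is the top-right lane; lane `q` of the forefront
at antidiagonal `p` holds cell `(i, j) = (toprightI - q, p - toprightI +
q)`.  Each step the forefront advances right (all lanes `i + 1`) or down
(`j + 1`); operand lanes realign by a one-lane shift depending on the
direction, and reads past the band edge substitute a large negative
constant so band-truncated cells can only be pessimistic -- they never
inflate a score.  The advance reads only the immediately preceding
forefront; the second-previous-vector dependence of the nondifference
recurrences disappears in difference form.

**Direction rule.** The engine compares the reconstructed absolute scores
of the two edge lanes and moves *toward the higher one* (top edge higher:
right; bottom higher: down), keeping the edge difference small and the
score peak centred.  An exact tie alternates with the previous direction,
which yields the characteristic zigzag along a perfect match diagonal.
Boundary clamps force down once the band reaches the right end of `a` and
force right at the bottom end of `b`.  The tie rule and the clamp
interaction are design choices of this package; the validation is
end-to-end (final score equality with the full DP), not per-decision.

**Score decomposition.** Absolute scores are stored as `L[k] + D[q] +
d[p,q]`: a per-block (32 vectors = 1024 cells at `W = 32`) large offset, a
per-lane middle delta fixed by the phantom-block initial conditions
(`phantomInit()`), and a per-cell small delta.  At each block seal the new
large offset is the floor-average of the reconstructed lane `W/4` and
`3W/4` values of the block's last vector and the small deltas are rebased;
if either reference lane lies outside the matrix the best in-matrix lane
value substitutes (rebasing is score-invariant, so the choice is
immaterial -- a property the tests assert directly).  Small-delta width is
nominally 8 bits; `bandConfig(deltaBits = 8)` enforces the emulation,
raising on positive overflow (which would corrupt maxima, e.g. with a
large-`M` matrix) and saturating on negative underflow (which only affects
lanes that have already lost, the saturating-SIMD behaviour).  The default
leaves arithmetic wide: this implementation is a correctness reference,
not a speed port.

**Maximum search and X-drop.** Per-lane block maxima of `d` are tracked
during the fill; `findMaxCell()` maximizes `L[k] + D[q] + maxd` and then
recomputes the winning block's small-delta vectors on demand from its
stored boundary state to locate the exact antidiagonal (the advance is
deterministic, so the refill is exact).  Ties resolve to smallest `i + j`
then smallest `i` -- deliberately identical to the reference engine's
documented tie-break so that banded and full-DP paths are comparable.
The fill terminates early when the best forefront score drops strictly
more than `X` below the running maximum (default `X = 50`).

**Traceback.** Four flag bits per cell (`mH`, `mV`, `mE`, `mF`) record
which transitions achieve the recurrence maxima, by equality tests on
difference values alone.  The traceback walks by logic only under the
strict priority *vertical > horizontal > diagonal*, extending a gap while
its extension flag permits.  This package stores the per-forefront flag
matrices during the fill (memory is not a design goal here) while keeping
the on-demand block refill for the maximum search; refill determinism --
recomputed flags identical to stored ones -- is itself a test.

**Band failure.** With `W = 32` the band can lose the optimal path on
hard regions (long gaps, low-identity stretches); this is inherent to
banded alignment.  On synthetic pairs with the package's default error
profile and gaps capped at 20, the band recovers the exact full-DP score
in well over 95% of trials (tested at 200 seeded 2 kb pairs); pairs
containing longer contiguous gaps are exactly the inputs a 32-lane band
is expected to lose, which is why the generator caps them by default.

## Path encoding and CIGAR

A path is emitted as bits: `1` vertical (consumes `b`), `0` horizontal
(consumes `a`), `10` diagonal.  Under the traceback priority a produced
path never contains a vertical transition immediately followed by a
horizontal one (the equal-scoring horizontal-then-vertical order always
exists and the priority picks it), which makes the encoding uniquely
decodable in both reading directions (`decodePath()`), and gives the
length identity `bits = consumed_a + consumed_b`.  `pathToCigar()`
converts runs by bit counting on 30-bit packed words -- zero runs are
deletions, one runs insertions, and XOR with the alternating `1010...`
mask of matching phase reduces a diagonal run to a zero run -- and is
checked against the symbol-by-symbol converter `pathToCigarNaive()`.
Horizontal maps to `D` and vertical to `I` (`a` is the reference);
diagonal is `M`, covering matches and mismatches (no `=`/`X` split).
Word width 30 keeps every packed word a positive R integer; the choice is
internal to the converter.

## Synthetic pairs

`generatePair()` draws a uniform ACGT reference and mutates it in one
walk: per position, an insertion run may open (default rate 0.014), the
position may be deleted (0.091) or substituted (0.061) -- the error
profile of filtered nanopore read pairs -- with geometric run lengths
truncated at `maxGap = 20`, mirroring the filtering that benchmark inputs
for 32-lane banded alignment receive.  The generating walk's CIGAR is
returned as ground truth; `pairSet()` derives per-pair seeds as `baseSeed
+ index` and writes byte-reproducible paired FASTA plus a truth table.
The generator matches marginal event rates only: real nanopore errors are
homopolymer- and repeat-biased, which this model deliberately omits, so a
passing band-recovery test says nothing about such regions.  All
randomness flows through one seeded generator; callers' RNG state is
restored.

## Numerical and testing choices

* All scores are integer-valued doubles; every equivalence assertion is
  exact.  The `-inf` sentinel is `-((|a|+|b|) * sum-of-gap-penalties + M
  + 1)`, too low to ever win a maximum in finite arithmetic.
* Ties inside every recurrence maximum resolve in the order the branches
  are written (diagonal, E, F); the maximum cell tie-breaks to smallest
  `i + j`, then smallest `i`, in every engine.
* Test problem sizes: the randomized equivalence sweep uses 500 instances
  of length 1-300; banded-versus-full-DP recovery uses 200 pairs of 2 kb
  (the 25 kb read regime scaled down; band mechanics are length-invariant
  across block seals, so the per-seal properties are exercised identically
  while the full-DP oracle stays cheap); decomposition exactness uses a
  2 kb pair under a matrix-covering band with over 60 block seals.
* The brute-force oracles are genuinely independent: an exhaustive
  depth-first enumeration over monotone move strings scores alignments
  directly from gap-run structure (never via recurrences), and `adist()`
  supplies the edit-distance cross-check for the unit-cost reduction.

## Limitations

Banded results are exact only when the optimal path stays inside the
band; the engine reports, not repairs, band failure (the score simply
falls short of the full DP).  Ambiguity codes, protein alphabets, local
(Smith-Waterman) alignment, seed chaining and SAM record emission are out
of scope.  The CLI (`exec/galign`) is a thin wrapper over the exported
functions: `align`, `simulate`, `diagnostics`, `selftest`, with flags or
a `key=value` config file.
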