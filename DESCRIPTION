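Package: diffalign
Title: Semi-Global Alignment via Difference Recurrence Relations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Semi-global Smith-Waterman-Gotoh alignment of nucleotide
    sequences with affine gap penalties, implemented in three mathematically
    equivalent formulations: the classical nondifference dynamic program, the
    naive difference recurrences that store differences between adjacent
    cells, and the offset difference recurrences whose values are all
    non-negative and bounded by a single constant. On top of the offset
    form the package provides an adaptive banded alignment engine with
    block-wise score decomposition and X-drop termination, a priority-driven
    bit-encoded traceback with path-to-CIGAR conversion, a dependency-graph
    analyzer for the per-cell critical path of each formulation, and a
    synthetic long-read pair generator with known true alignments. Exact
    cross-formulation equivalence is the correctness contract and is
    exercised throughout the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'path.R'
    'cigar.R'
    'encode.R'
    'scoringScheme.R'
    'reference.R'
    'diffNaive.R'
    'diffOffset.R'
    'band.R'
    'traceback.R'
    'align.R'
    'criticalPath.R'
    'diagnostics.R'
    'diffalign-package.R'
    'fasta.R'
    'synthetic.R'
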