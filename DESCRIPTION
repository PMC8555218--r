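Package: depthCNV
Title: Read-Depth CNV Calling with Consensus-Driven Parameter Optimization
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects germline copy-number variants (deletions and
    duplications) from per-target read counts of targeted or whole-exome
    capture panels. Provides a transparent read-depth caller (reference
    sample selection by correlation, median-coverage QC, reads-ratio
    normalization and three-state hidden Markov segmentation), construction
    of an in silico validation set from the consensus of multiple caller
    outputs, grid-search optimization of the caller's three tunable
    parameters against that validation set to maximize sensitivity, per-ROI
    confusion-matrix benchmarking, and a negative-binomial cohort simulator
    so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
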