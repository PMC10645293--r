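Package: HiCLoopPower
Title: Power Analysis and Experiment Design for Differential Hi-C Loop Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for planning comparative Hi-C experiments aimed at
    detecting differential chromatin loops. Models the compression of
    looping fold changes into observed-count fold changes caused by the
    distance-dependent polymer background, computes closed-form per-loop
    power for two-condition comparisons of overdispersed (negative
    binomial) counts, sweeps sequencing-depth by replicate by dispersion
    grids to report the fraction of well-powered loops, estimates a
    common dispersion from replicate count matrices, thins contact-record
    streams to target depths, and generates calibrated synthetic loop
    sets so every step is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    jsonlite
Config/testthat/edition: 3
biocViews: HiC, Epigenetics, StatisticalMethod, ExperimentalDesign
RoxygenNote: 7.3.3
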