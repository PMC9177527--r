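Package: replifork
Title: Single-Molecule Replication Fork Detection, Speed Measurement and
    Genome-Wide Mapping from Nanopore BrdU Pulse-Chase Traces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects, orients and measures the velocity of individual DNA
    replication forks from per-thymidine BrdU probability traces produced by
    nanopore sequencing of pulse-chase labelled DNA. Reads modified-base BAM
    (MM/ML tags) or tabular traces, smooths them, simplifies them into
    classified linear segments (Ramer-Douglas-Peucker), calls oriented forks
    by pattern matching, and aggregates forks into genome-wide replication
    fork directionality and multi-scale fork-speed maps with permutation
    envelopes and Mann-Whitney significance calls. Includes a pulse-chase
    fork-signal simulator with an empirically calibrated noise model, and a deconvolution
    procedure that estimates the true fork-speed distribution from measured
    speeds via simulated response libraries, non-negative least squares and
    Gaussian-mixture fitting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    mclust,
    pracma,
    Rsamtools,
    GenomicAlignments,
    BiocGenerics,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
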