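Package: regloop
Title: Regulatory-Loop Analysis of Transcription-Factor Binding, Expression and Boolean Circuit Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing transcription-factor regulatory circuits from
    tiling-array ChIP-chip and expression microarray data. Implements probe-level
    signal processing (quantile normalization, median replicate pooling, running
    median smoothing, mock-control subtraction), threshold-and-merge peak calling,
    peak-to-gene association and feature enrichment against random-placement
    nulls, block-bootstrap basepair-overlap statistics, hypergeometric gene-set
    overlap, differential-expression selection with batch covariates and
    Benjamini-Hochberg FDR cutoffs, and synchronous Boolean network simulation
    with node clamping for linear and feed-forward regulatory models. A seeded
    synthetic-data generator produces genomes, probe maps, planted-peak ChIP
    tracks and expression matrices so that every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    limma,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
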