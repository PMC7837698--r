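Package: clockcells
Title: Rhythmicity Detection and Annotation for Single-Cell Circadian
    Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-alignment analysis of single-cell RNA-seq circadian time
    courses of the Drosophila clock-neuron network: entropy-based cell quality
    control, TP10K normalization, pseudo-bulk reconstruction, per-cluster
    detection of 24-hour cycling transcripts (a permutation JTK test treating
    cells as replicates, a pseudo-replicate-split Fourier F24 score, and
    amplitude and peak-expression gates), one-vs-rest marker detection, and
    rule-based anatomical annotation of clock-neuron clusters including the
    constant-darkness antiphase criterion for DN2 neurons.  A seeded
    negative-binomial simulator with planted cyclers, markers and quality-
    control failures makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    methods,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
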