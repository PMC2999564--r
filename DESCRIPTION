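Package: estarray
Title: Transcriptome-Wide Oligonucleotide Probe Design and
    Hybridization-Based Validation from EST Collections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds species-specific oligonucleotide microarray probe sets
    for organisms that have transcriptome-scale expressed sequence tag (EST)
    collections but no reference genome. Provides BLASTN-like local
    alignment with ungapped Karlin-Altschul statistics for assembly
    completeness and correctness testing, deterministic 40/60-mer probe
    design with array-layout accounting, a one-color hybridization simulator
    with spike-in controls and photomultiplier gain effects, spike-in
    calibrated present/absent/saturated calling, and the six-step reduction
    of tested probes to a unique, validated probe per unique target,
    including a cross-hybridization similarity filter with an exhaustive
    audit oracle. Six-frame open-reading-frame extraction prepares targets
    for downstream annotation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
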