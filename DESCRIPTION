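Package: wgpmap
Title: Whole Genome Profiling Physical Mapping and Sequence Scaffolding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for sequence-based (Whole Genome Profiling) physical
    mapping of large repetitive genomes. Simulates BAC libraries,
    three-dimensional plate pooling and barcoded restriction-site tag
    sequencing; deconvolutes pooled tag observations to individual BACs and
    applies tag- and clone-level quality filters; assembles clone contigs
    with the Sulston coincidence score using a stepwise stringency protocol
    with DQing and end merging; evaluates map quality against reference
    sequence (chimeric contigs, mis-assembled clones, consensus-band unit
    calibration, tag landscape, N90/L90, k-mer uniqueness); and integrates
    tags into draft sequence assemblies to build superscaffolds and assign
    scaffolds to their BAC of origin.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
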