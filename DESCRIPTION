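Package: quadtractMA
Title: G-Quadruplex Motif Scanning and Mutation-Accumulation Analysis for
    Helicase-Deficient Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing mutation accumulation in guanine-rich DNA.
    Scans genomes for G-quadruplex (G4) signature motifs, relaxed G-run
    signatures and monoG/C homopolymer tracts; filters per-generation
    variant-caller output into fixed homozygous variant sets and builds
    cross-generation accumulation matrices; classifies large deletions by
    the G-rich motif at which they initiate; estimates per-base, per-gene
    and per-site mutation rates, transition/transversion ratios and
    mutation spectra; counts protein-coding genes impacted by each variant
    class; and simulates mutation-accumulation lines on toy genomes with
    planted motifs so that every stage of the pipeline can be validated
    against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    VariantAnnotation,
    SummarizedExperiment,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
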