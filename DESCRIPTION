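Package: StructExpr
Title: Spatial Expression Analysis of Structured RNA Transcripts in a Voxel Brain Atlas
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Links in-silico predicted RNA secondary structures to spatial gene
    expression in a three-dimensional voxel brain atlas. Classifies in situ
    hybridization probes against gene models (intergenic, intronic, UTR, CDS),
    maps strandless structure predictions and known-RNA annotations onto probes,
    computes voxel expression energy, region aggregates and spatial enrichment
    scores, tests region-wise group differences with percentile-t bootstrap on
    trimmed means under Benjamini-Hochberg control, builds voxel co-expression
    correlation networks with data-driven threshold selection and expression
    module detection, scans UTR structure neighborhoods for RNA-binding-protein
    motifs, and scores RNA-RNA interaction sites against dinucleotide-shuffled
    backgrounds using censored extreme-value-distribution calibration. A
    synthetic atlas generator produces every input with known ground truth so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
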