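Package: emalescan
Title: Discovery and Classification of Endogenous Virophages and Ngaro
    Retrotransposons in Host Genome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects, delimits, classifies and quantifies endogenous
    mavirus-like elements (EMALEs) and Ngaro (DIRS-order) tyrosine
    recombinase retrotransposons in high-GC protist genome assemblies.
    Provides sliding-window GC anomaly screening, six-frame ORF calling
    with protein homology confirmation, terminal inverted repeat and
    target site duplication delimitation, word-match dot-plot typing,
    split-direct-repeat resolution of retrotransposon insertions,
    integration-site enrichment statistics, and assembly- and read-based
    nucleotide contribution accounting. Ships a synthetic genome
    generator that plants elements with known ground truth so that every
    stage of the pipeline is verifiable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.3)
Imports:
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    GenomicAlignments,
    Rsamtools,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
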