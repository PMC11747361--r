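Package: gapseqr
Title: Gap-Targeted Long-Read Scaffolding and Population-Genomic Window Scans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for finishing fragmented plant genome assemblies with
    gap-targeted nanopore adaptive sampling (GAP-Seq). Designs contig-end
    target regions (plain and repeat-aware), filters long reads by length and
    mean quality, joins contigs with a k-mer-pair link scaffolder, bridges
    scaffolds across two assemblies into super-scaffolds, anchors them to a
    related reference into pseudomolecules, and provides assembly QC
    (Nx statistics, k-mer-histogram genome-size estimation, telomere end
    scanning). Also includes sliding-window Tajima's D and Weir-Cockerham
    F_ST with permutation-based outlier detection, and seeded synthetic-data
    generators so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    data.table,
    igraph,
    vcfR,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
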