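Package: pointcen
Title: Discovery and Analysis of Unconventional Point Centromeres
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for locating and characterising budding-yeast point
    centromeres from kinetochore ChIP enrichment. Implements single-peak
    enrichment calling on binned ChIP/input coverage with primary/secondary
    tiers and intergenic classification, ungapped anchor alignment of
    candidate centromere sequences, position-frequency-matrix column
    classification and degenerate IUPAC consensus derivation, genome-wide
    degenerate motif scanning with uniqueness reporting and element-directed
    mutagenesis in window coordinates, and gene-order synteny classification
    of centromere loci against a reference genome. A synthetic-data module
    generates genomes, annotations, planted centromeres and coverage tracks
    with machine-readable truth for validation, and a pipeline runner
    orchestrates the full simulate-call-align-scan-classify chain.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    GenomeInfoDb,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
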