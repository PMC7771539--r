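Package: BarSeqTools
Title: Design and Quantification of Barcode-Tagged In-Frame Gene Deletions
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Toolkit for multiplexed strain competition experiments with
    barcode-tagged in-frame gene deletions (BarSeq). Designs semirandom
    18-nt barcodes from VNN codons so that deletion scars carry no in-frame
    stop codon, designs the eight deletion oligos and assembles the marked
    (erm-bar) and unmarked (bar) FLP/FRT deletion scars and SOE-PCR
    fragments in silico, counts barcodes in amplicon FASTQ reads by
    flank-anchored extraction against a strain-barcode library, and
    computes relative frequencies and log10 competitive indices. A
    synthetic-data module simulates pooled competitions, bottlenecks, and
    error-bearing amplicon reads so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3), SummarizedExperiment
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    S4Vectors,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
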