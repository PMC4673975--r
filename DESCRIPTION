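Package: txbench
Title: Benchmarking Toolkit for Full-Length Transcript Reconstruction from RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds ground-truth gene annotations with controlled alternative
    splicing, simulates strand-specific paired-end RNA-Seq reads with
    configurable polymorphism, sequencing-error and intron-signal rates
    (including perfect truth alignments in SAM format), corrupts annotation by
    hiding expressed transcripts and planting unexpressed decoys, and scores
    predicted transcript sets (GTF) against truth using junction-chain
    precision/recall and FPKM-agreement metrics, stratified by splicing event
    category, forms per gene and depth of coverage.
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
    optparse,
    rtracklayer,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
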