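Package: drnatss
Title: Primary Transcriptome Analysis from dRNA-Seq 5'-End Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Calls bacterial transcription start sites (TSSs) from paired
    TEX-treated (primary) and untreated (minus) dRNA-Seq 5'-end count
    tracks using a replicate-aware enrichment criterion with background
    control, classifies TSSs against a genome annotation (gTSS, iTSS,
    aTSS, nTSS), computes 5'-UTR lengths and leaderless-transcript /
    start-codon re-annotation calls, tests differential TSS expression
    across growth conditions under a negative-binomial model with
    median-of-ratios normalization and Benjamini-Hochberg correction, and
    summarizes condition overlap, initiation-nucleotide usage and ranked
    transcript abundance. Includes a synthetic dRNA-Seq generator with
    planted ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    Rsamtools,
    DESeq2
Config/testthat/edition: 3
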