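Package: tmseq
Title: Transcriptional Mutagenesis Detection from UMI-Tagged Single-Cell
    and Rolling-Circle RNA Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects transcription errors (transcriptional mutagenesis) from
    RNA sequencing data in which every original mRNA molecule is tagged with a
    unique molecular identifier (UMI) and a cell barcode. Reads sharing a
    (cell barcode, UMI, transcript) key are collapsed into molecule consensus
    sequences, RNA-DNA discrepancies are called against reference transcripts,
    sites dominated by mutant molecules are excluded as candidate DNA
    mutations, and the twelve base-substitution error rates per transcribed
    base are estimated and compared between conditions with an unpaired
    t-test. Per-cell mutant:wild-type molecule ratios identify pseudo-alleles,
    lesion-bearing sites that yield both wild-type and recurrently mutant
    transcripts. A companion rolling-circle consensus (CirSeq) module folds
    tandem-repeat reads into intra-read consensus sequences for bulk RNA error
    rates. A forward simulator generates barcoded single-cell reads and
    rolling-circle reads with known lesion, DNA-mutation, transcription, PCR
    and sequencing error parameters, so every stage is testable against ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    ggplot2,
    generics,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vctrs,
    yaml
LinkingTo:
    Rcpp
Suggests:
    Biostrings,
    Rsamtools,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
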