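Package: hervrec
Title: Reconstruction and Classification of HERV-K (HML-2) Rec Open Reading Frames
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in-silico pipeline for characterising the Rec open reading frames
    encoded by HERV-K (HML-2) proviruses. Proviral genomes are globally aligned to
    annotated type-2 and type-1 (292-bp deletion) reference genomes with an
    affine-gap aligner, annotations are transferred through the alignment, the
    diagnostic pol-env deletion is detected and proviruses are typed. For type-2
    loci the Rec transcript is rebuilt by in-silico GT-AG splicing (with an
    exon-1/env readthrough fallback when a splice site is mutated), translated,
    screened for premature stops and frameshifts, partitioned into full-length and
    truncated proteins, deduplicated, and protein variants are called against the
    consensus Rec with compact substitution/deletion/insertion labels. The package
    also implements the quantification maths of the accompanying dual-fluorescence
    reporter assay (event gating, GFP/eBFP2 MFI ratios, expression-normalised MFI,
    trans-dominant dose-response normalisation, and 4-parameter-logistic p24
    standard curves), and ships truth-labelled synthetic data generators so every
    stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    minpack.lm,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
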