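Package: CAHscreen
Title: Paralog-Aware Long-Read Amplicon Screening for 21-Hydroxylase
    Deficiency
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for long-read amplicon based newborn screening of
    congenital adrenal hyperplasia on a desk-scale model of the
    CYP21A2/CYP21A1P locus. Builds a paired functional-gene/pseudogene toy
    reference with paralog signature variants (PSVs), simulates barcoded
    high-accuracy circular-consensus amplicon reads for arbitrary
    diplotypes (including 30-kb-deletion chimeras, gene-conversion
    chimeras and fusion-duplication carriers), classifies reads by primer
    pairs, aligns them with a banded affine-gap fitting aligner, calls
    small variants with a coverage floor, localises chimera junctions by
    minimum-mismatch changepoint over PSV states, phases reads into
    haplotypes for cis/trans reporting, renders duplication-aware
    screening verdicts, and computes cohort screening statistics with
    Jeffreys-prior Beta posteriors for sensitivity and specificity.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
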