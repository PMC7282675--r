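Package: metscreen
Title: Metastasis-Driver Screening in Matched Primary-Tumor / Metastasis Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering candidate metastasis-driver events in
    matched primary-tumor / lung-metastasis pairs from F1-hybrid mouse
    models of breast cancer. Implements a consensus single-nucleotide
    variant screen across three callers with a seeding-cell variant-allele
    -fraction filter and recurrence classification, allele-specific
    copy-number segmentation from strain-informative heterozygous SNP
    counts with recurrent-region intersection across animals, curation of
    candidate gene fusions and structural variants (read-through,
    repeat-breakpoint and gene-family artifact classes), and CNV/SNV
    fingerprint clustering for per-animal mono- versus polyclonal seeding
    calls. A fully specified synthetic-cohort generator with planted
    ground truth exercises every stage end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    jsonlite,
    generics,
    stats,
    utils,
    vcfR,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
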