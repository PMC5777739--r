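Package: lineconcord
Title: Genomic Concordance of Cancer Cell Lines and Tumors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores how faithfully cancer cell lines represent tumor cohorts
    at the genomic level. Implements single-sample enrichment (ssGSEA) scoring
    of stromal and immune signatures with conversion to an estimated tumor-cell
    fraction and purity filtering; fraction genome altered (FGA) from segmented
    copy number; projection of copy-number segments onto genes and Pearson
    concordance between cell lines and tumors over all genes or a focal-peak
    subset; differential-mutation testing (two-sided Fisher exact, log-space),
    exact mid-p mutual-exclusivity testing of gene pairs, coverage-normalized
    tumor mutational burden from BED/WIG coverage, and UV mutational-signature
    classification. Includes a seeded synthetic-cohort generator that emits
    paired tumor/cell-line MAF, SEG, coverage, and expression files with known
    ground truth, and an end-to-end pipeline with deterministic outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
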