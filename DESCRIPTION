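Package: crcmetrics
Title: Cohort Metrics for Colorectal Cancer Whole-Genome and Transcriptome Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reusable implementations of cohort-level analysis procedures for
    population-scale colorectal cancer genomics: iterative quantile-based
    hypermutation classification, tumour mutation burden, allele-specific
    copy-number state taxonomy and genome-altered-fraction density metrics,
    mitochondrial somatic-variant filtering against NuMT artifacts with
    data-driven cutoffs and mtDNA copy-number estimation, Buffa hypoxia
    scoring with a nested-linear-model association framework, mutational
    signature similarity and novelty assessment, pairwise co-mutation
    testing, survival endpoint derivation and maximally selected rank
    statistic cutpoints. Includes a seeded synthetic cohort generator so the
    whole pipeline is testable without access-restricted patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    IRanges,
    S4Vectors,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
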