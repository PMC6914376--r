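Package: nbsval
Title: Analytical Validation of Targeted Newborn-Screening Sequencing Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the analytical validation of small targeted
    next-generation sequencing panels of the kind used for newborn
    bloodspot screening. Provides variant decomposition and
    left-align/trim normalization, construction of padded exon panels and
    restriction of call sets to panel regions, post-hoc variant-caller
    threshold filtering, truth-set benchmarking with base-level
    true-negative accounting (sensitivity, specificity, Matthews
    correlation coefficient), coverage-stratified concordance between
    paired dried-blood-spot and venous-blood call sets, per-sample
    coverage QC tiering, and a deterministic laboratory
    throughput/turnaround/cost model. A fully seeded synthetic-data
    generator emulates panels, truth sets, error-injected call sets and
    per-base depth tracks, with a ground-truth ledger for exact recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    rtracklayer,
    vcfR,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
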