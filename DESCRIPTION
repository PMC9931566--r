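Package: lcnet
Title: Characterizing Uptake of the Long COVID Diagnosis Code with
    Co-Occurrence Networks and Disparity Statistics
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterize the early clinical use of a newly
    released diagnosis code (ICD-10-CM U09.9, post COVID-19 condition)
    in observational EHR extracts: cohort construction around a code
    index date with inpatient-index exclusions and site-quality gates,
    diagnosis co-occurrence networks over the most frequent in-window
    conditions with in-package Louvain, Girvan-Newman, and Walktrap
    community detection, area-level social-determinants-of-health
    categorization with G-test disparity comparisons and small-cell
    disclosure control, procedure and new-medication summaries with ATC
    level-3 rollup, and code-uptake time series. Ships a synthetic
    OMOP-flavored EHR generator with planted symptom-subtype structure
    so every stage is testable without access-restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils
Suggests:
    igraph,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
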