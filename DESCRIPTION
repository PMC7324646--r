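Package: panelvar
Title: Tumor-Only Variant Interpretation for Targeted Myeloid Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Interpretation pipeline for ultra-deep targeted myeloid-panel
    sequencing of tumor-only (unmatched) leukemia specimens. Implements staged
    quality and population-allele-frequency filtering, a blast-fraction-based
    somatic versus germline classifier, clonal ordering of co-existing somatic
    mutations from variant allele fractions, consequence and conservation
    profiling with nonsynonymous/synonymous ratio comparison, a multi-evidence
    germline prioritization cascade, cohort-level recurrence and mutation-burden
    statistics (Kruskal-Wallis with Dunn post hoc), and pharmacogenomic genotype
    reporting. Ships a seeded synthetic-cohort generator with known
    somatic/germline truth so every stage is testable without protected
    patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
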