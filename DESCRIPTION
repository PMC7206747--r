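Package: adhfphenotype
Title: Rule-Based Computable Phenotyping for Acute Decompensated Heart
    Failure in Hospitalized Patients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a computable phenotype for acute decompensated
    heart failure (ADHF) over sectioned clinical notes: a Boolean
    free-text search with configurable inclusion terms, exclusion-cue
    scoping (sentence or token-window), restriction to designated note
    sections, and admission-level aggregation. Ships ICD-9 code-set
    comparator strategies (acute heart-failure codes and all 428-family
    codes), a diagnostic-accuracy evaluation layer (2x2 tables,
    sensitivity and specificity with exact Clopper-Pearson confidence
    intervals, strategy comparison tables, discordance reports for
    iterative dictionary refinement), a cohort-eligibility filter, and a
    seeded synthetic EHR generator producing sectioned notes, ICD-9
    codes and ground-truth labels so the full derivation/validation
    protocol runs without access to protected health information.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tibble,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
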