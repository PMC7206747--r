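# adhfphenotype

Rule-based computable phenotyping for **acute decompensated heart failure
(ADHF)** in hospitalized patients, with the ICD-9 comparator strategies and
the diagnostic-accuracy machinery needed to derive and validate the
phenotype against a reference standard.

## Who this is for

Clinical-informatics and outcomes researchers who need to find ADHF
admissions in an EHR at a scale where manual chart review is impossible and
ICD-9 codes are untrustworthy: the 428 family marks *acute* heart failure
only in its fourth/fifth digits (`428.21`, `428.23`, `428.31`, `428.33`,
`428.41`, `428.43`), and coders often fall back on the unspecific members,
so acute codes miss roughly half of true ADHF admissions while the full
family is sensitive but unspecific. A free-text search over the note
sections that assert diagnoses does substantially better — if its term
lists are derived and validated carefully. This package implements that
search and the validation protocol around it.

## The method

An admission is ADHF-positive iff some note section in scope contains an
inclusion phrase that no exclusion cue suppresses:

* **Section scoping** — only principal diagnosis, secondary diagnoses,
  chief complaint / reason for visit, and brief hospital course are
  searched (configurable).
* **Inclusion terms** — whole-token phrase matches over normalized text
  (case, whitespace, typographic variants), longest-leftmost on overlap;
  the default list covers the standard ADHF surface forms and acronyms.
* **Exclusion cues** — `prior`, `rule out`, `negative for` (plus
  configurable paraphrases); a cue in the same sentence as a match
  (or, optionally, within a token window before it) suppresses the match.
  Suppressed matches stay in the evidence trail for review.

Strategies are evaluated with the prevalence-free pair

    Sensitivity = TP / (TP + FN)        Specificity = TN / (TN + FP)

with exact (Clopper–Pearson) 95% confidence intervals. Discordance reports
(mismatches vs the reference, with evidence) drive the iterative
term-list refinement loop, whose conventional stopping rule is
sensitivity > 95%. A seeded synthetic EHR generator produces sectioned
notes, imperfect ICD-9 codes and ground-truth labels so the whole
protocol — simulate, phenotype, code comparators, evaluation,
discordance review — runs with no real patient data.

## Worked example

```r
library(adhfphenotype)

note <- clinical_note(
  note_id = "n001", admission_id = "adm42",
  timestamp = "2011-02-03T08:00:00",
  text = paste0("Chief Complaint/Reason for Visit: Dyspnea and weight gain.\n",
                "Principal Diagnosis: Acute decompensated heart failure.\n",
                "Secondary Diagnoses: Rule out ADHF was the ED impression.\n",
                "Family History: Mother with ADHF.\n"))

verdict <- classify_admission(list(note), default_dictionary())
verdict
#> <phenotype_verdict> admission adm42: ADHF positive (1 kept, 1 suppressed match)
verdict$suppressed_matches[, c("term", "section_name", "suppressed_by")]
#> # A tibble: 1 × 3
#>   term  section_name        suppressed_by
#>   <chr> <chr>               <chr>
#> 1 adhf  secondary_diagnoses rule out
```

The principal-diagnosis mention is kept (hence the positive verdict), the
"rule out" mention is suppressed with its cue recorded, and the
family-history mention never enters: that section is out of scope.

On a synthetic cohort with known truth, the phenotype and the acute-code
comparator separate exactly as expected — text search nearly perfect,
acute codes sensitive to barely half the cases:

```r
co    <- generate_cohort(cohort_spec(n_patients = 500, seed = 42))
pred  <- verdict_predictions(run_phenotype(co$notes, matched_dictionary()))
acute <- run_code_strategy(co$admissions, acute_hf_codes())
rows  <- compare_strategies(reference_vector(co$truth),
                            list(eadhf = pred, icd9_acute_hf = acute),
                            cohort_label = "synthetic")
writeLines(render_comparison(rows))
#> | Cohort | Strategy | Reference | n | Sensitivity % (95% CI) | Specificity % (95% CI) |
#> |---|---|---|---|---|---|
#> | synthetic | eadhf | reference_standard | 500 | 98.4 (95.4-99.7) | 100.0 (98.8-100.0) |
#> | synthetic | icd9_acute_hf | reference_standard | 500 | 44.9 (37.7-52.3) | 100.0 (98.8-100.0) |
```

`run_full_protocol()` (or the `inst/cli/phenotype` script's `protocol`
subcommand) runs the same workflow from files on disk and writes the
comparison tables, a Markdown report, the discordance file and a
provenance record.

## Package layout

* `R/` — domain types and readers (`clinical_note`, corpora, code lists,
  labels), the matching engine, ICD-9 comparators, evaluation layer,
  synthetic generator, protocol runner.
* `inst/cli/phenotype` — command-line wrapper
  (`simulate | run | icd9 | evaluate | compare | protocol`).
* `vignettes/adhf-phenotyping.Rmd` — the methods vignette: model,
  assumptions, parameter defaults and their rationale, numerical choices,
  limitations.
* `tests/testthat/` — unit, property and acceptance tests, including an
  independently written brute-force oracle for the engine.
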