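---
title: "A computable phenotype for acute decompensated heart failure: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A computable phenotype for acute decompensated heart failure: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adhfphenotype)
```

## The problem

Acute decompensated heart failure (ADHF) — the sudden or gradual worsening
of heart-failure signs and symptoms that forces an unplanned hospital
admission — is a common target condition for retrospective EHR research,
and a frustrating one to ascertain. ICD-9 coding distinguishes *acute* from
*chronic* heart failure only in the fourth and fifth digits of the 428
family, and coding practice rarely bothers: most ADHF admissions carry
some heart-failure code, few carry the specifically acute one. Manual chart
review is accurate but cannot scale to hundreds of thousands of admissions.

A *computable phenotype* is the middle road: an executable, rule-based
definition that reads the clinical notes themselves. This package
implements such a phenotype for ADHF in hospitalized patients — a Boolean
free-text search with a curated term dictionary — together with the ICD-9
code strategies it is conventionally benchmarked against, the
diagnostic-accuracy layer used to validate all of them against a reference
standard, and a synthetic EHR generator so the whole derivation/validation
protocol runs end to end with known ground truth and no protected health
information.

## The phenotype rule

An admission is called ADHF-positive when at least one **inclusion phrase**
occurs in a **scoped section** of any of its notes and is not suppressed by
an **exclusion cue**. Concretely, for every note of the admission:

1. **Section scoping.** Only sections whose canonical name is in the
   dictionary's `scoped_sections` are searched. The defaults are the four
   places a discharge summary asserts its diagnoses: principal diagnosis,
   secondary diagnoses, chief complaint / reason for visit, and brief
   hospital course. A mention in a family-history or medications section is
   never evidence.
2. **Normalization.** Section text is lowercased; whitespace runs collapse
   to single spaces; curly quotes and Unicode dash variants are unified.
   The transformation keeps a per-character offset map, so every reported
   match can be located in the original note.
3. **Inclusion matching.** All occurrences of the inclusion phrases are
   found as whole-token substrings (so `adhf` never matches inside
   `BADHFX`). Where phrases overlap, the longest match at the leftmost
   position wins and scanning resumes after its end.
4. **Exclusion scoping.** A match is suppressed when an exclusion cue
   occurs in its scope. The default scope is the *sentence* containing the
   match; a token-window mode (cue within `window_tokens` tokens before the
   match, counted from the end of the cue) is available. Suppressed matches
   are retained in the verdict's evidence with the suppressing cue named,
   because the refinement workflow reviews them.
5. **Aggregation.** The admission is positive iff any kept match exists
   across its notes. The verdict is deterministic and independent of note
   order.

The shipped dictionary covers the standard surface forms of ADHF ("acute
decompensated heart failure", "decompensated CHF", "heart failure
exacerbation", the acronym "ADHF", and so on) and three core exclusion
cues — `prior`, `rule out`, `negative for` — marking historical,
speculative and negated mentions, plus a few common paraphrases
(`history of`, `no evidence of`, `ruled out`, `r/o`, `resolved`). Term
lists are institution-specific by nature: everything is configurable
through `term_dictionary()` or a YAML/JSON file, and the defaults are a
starting point, not a claim of portability.

## Comparator strategies and evaluation

Two ICD-9 strategies classify an admission from its code list alone:

* **acute HF codes** — `428.21`, `428.23`, `428.31`, `428.33`, `428.41`,
  `428.43`: the fifth-digit "acute" and "acute on chronic"
  systolic/diastolic/combined codes, i.e. the heart-failure family minus
  its chronic and unspecified members;
* **all HF codes** — the hierarchical prefix `428`.

Hypertensive heart disease with heart failure (402.x1, 404.x1/x3) is
deliberately not in the default all-HF set; a custom `code_set()` can add
it. Code matching is exact-string on the dotted form — trailing zeros are
significant, because `428.0` and `428.00` are distinct codes in coded data.

Every strategy is evaluated against a reference standard by the usual 2×2
table with the reference as column truth:

$$\mathrm{Sensitivity} = \frac{TP}{TP+FN}, \qquad
  \mathrm{Specificity} = \frac{TN}{TN+FP},$$

each with an exact Clopper–Pearson interval from beta quantiles
($\mathrm{qbeta}(\alpha/2;\,k,\,n-k+1)$ and
$\mathrm{qbeta}(1-\alpha/2;\,k+1,\,n-k)$, with the conventional 0 and 1 at
$k=0$ and $k=n$). Predictive values are intentionally absent from default
reports: they depend on the cohort's prevalence and do not transport
across settings; `compare_strategies()` reports only the two prevalence-free
metrics. The comparison table supports using one strategy as the reference
for another (ICD-9 vs the text phenotype), which is how coding quality is
audited once the text phenotype is trusted.

`discordance_report()` lists the admissions where a strategy and the
reference disagree, carrying the engine's evidence. This powers the
derivation loop: review false negatives to find missing surface forms,
review false positives to find missing exclusion cues, re-run, and stop
when sensitivity exceeds the 95% goal.

## The synthetic cohort generator

`generate_cohort()` emulates the data regime the phenotype is meant for,
with ground truth drawn *before* any text is rendered:

| parameter | default | meaning |
|---|---|---|
| `prevalence` | 0.40 | P(admission is a true ADHF case) |
| `p_document` | 0.975 | P(case documented with an affirmed form in a scoped section) |
| `p_negated_mention` | 0.15 | P(control carries a negated/historical mention) |
| `p_out_of_scope_mention` | 0.05 | P(mention lands only in a non-scoped section) |
| `p_acute_code_given_case` | 0.475 | P(case gets an acute 428 code) |
| `p_anyhf_code_given_case` | 0.975 | P(case gets any 428 code) |
| `p_anyhf_code_given_control` | 0.133 | P(control gets a chronic 428 code) |
| `minor_fraction` | 44867/314988 | P(patient under 18 at admission) |
| `unauthorized_fraction` | 13678/270121 | P(adult without research authorization) |

The defaults encode the regime the method addresses: text documentation of
true cases is nearly complete, which is what makes a note search viable;
coding is sensitive for heart failure in general but poor at marking
acuity, so the acute code set misses roughly half the cases while the
all-HF set is sensitive but unspecific; and a noticeable minority of
negative admissions mention ADHF only to negate it, which is what the
exclusion cues exist for. The negated/out-of-scope rates are not quantities
a coding audit reports; 15% and 5% were chosen once as clinically plausible
and left alone. Prevalence is set at the enriched level typical of a
reviewed validation sample, not the population rate.

Notes are templated — a header per section, one of at least three template
sentences per section, an affirmed mention rendered in a uniformly chosen
scoped section, a negated mention rendered as "`<cue> <form>`" inside a
sentence. That is deliberate: the engine operates on surface forms and
sections, not discourse, so template variety guards tests against
overfitting to one string without pretending to model clinical language.
What passing tests on this corpus demonstrate is that the engine
implements its stated rule exactly and recovers known truth under the
stated noise model; they say nothing about the coverage of any particular
term list on real notes, about misspellings, telegraphic styles, copy-forward
text, or negation expressed without a cue phrase. The `source` field on
labels (`synthetic_truth` vs `manual_review`) keeps that distinction
explicit in every output.

`generator_manifest()` declares the generator's vocabulary — surface
forms, cues, section layout, code pools — so tests can build a matched
dictionary or a deliberately impoverished one and run the refinement loop
against known truth.

## Numerical and design choices

* **Sentence splitting** is deterministic: boundaries at `.`, `;`, `!`,
  `?` and line breaks, with a guard so a period between two digits
  (a dose, "12.5 mg") does not split. No abbreviation lexicon: a
  reproducible rule beats a marginally smarter one that cannot be
  re-implemented as an independent oracle. A collapsed line break acts as
  both a space (for matching) and a sentence boundary (for scoping), so a
  phrase that straddles a line break can match while a cue does not reach
  across it.
* **Exclusion scope** defaults to the sentence because cue-and-finding
  almost always share one; the window mode exists for section styles with
  long run-on lines. Published descriptions of institutional free-text
  search tools rarely state their suppression scope; sentence scope is the
  more conservative (more suppressing) choice of the two on short
  diagnosis lines.
* **Tie-breaks**: longest inclusion match at the leftmost position; the
  suppressing cue reported is the earliest in scope, ties to the longest.
  Both choices exist only to make evidence deterministic — the binary
  verdict does not depend on them.
* **Offsets** are 0-based half-open in all interchange formats and match
  tables (JSON Lines corpora are consumed by more than one language);
  `section_text()` and the offset map keep R users out of manual indexing.
* **Age** is whole years at first admission (the threshold exclusion needs
  a reference date; first admission is the least surprising choice), and
  the age exclusion is applied before the authorization exclusion so the
  two counts partition the excluded set. Research authorization is treated
  as a per-patient attribute.
* **Degenerate inputs**: empty corpora and empty admissions yield negative
  verdicts, not errors; a metric whose denominator is zero (no reference
  positives, say) raises an error rather than returning `NaN`; reference
  admissions without predictions are an error, predictions without labels
  are dropped with a logged count (a strategy may legitimately cover more
  admissions than were reviewed).

## Problem sizes

The test suite and the acceptance script size their simulations to be
informative while staying quick: golden-rule checks run on handwritten
notes; oracle-equivalence runs 100 corpora of at most 50 notes against an
independently written sentence-scanner; accuracy recovery uses cohorts of
200 (noiseless), 1000 (refinement loop) and 2000 (coding model)
admissions; generator calibration uses 5000 admissions with a
three-standard-error band; the interval implementation is checked against
independent oracles for every $0 \le k \le n \le 50$.

## Known limitations

* Phrase-level matching only: no stemming, no spelling correction, no
  general negation grammar (NegEx/ConText-style rules with scope
  terminators are out of scope — the phenotype is a fixed term list by
  design, and its portability rests on re-deriving that list per
  institution).
* ICD-9 only; no ICD-10 mapping, no weighting by billing position.
* The synthetic corpus validates mechanism, not term coverage (see above).
* One label per admission; inter-reviewer disagreement in the reference
  standard is not modeled.
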