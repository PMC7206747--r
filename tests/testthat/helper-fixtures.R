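# In-code fixtures shared across test files.

# A tiny hand-written corpus: admission ids map to the scenario they encode.
fixture_notes <- function() {
  list(
    clinical_note("n1", "adm_pos", "2010-03-01T09:00:00",
      "Principal Diagnosis: Acute decompensated heart failure.\nBrief Hospital Course: Diuresed well."),
    clinical_note("n2", "adm_neg_section", "2010-03-02T09:00:00",
      "Principal Diagnosis: Pneumonia.\nFamily History: Mother with ADHF."),
    clinical_note("n3", "adm_prior", "2010-03-03T09:00:00",
      "Principal Diagnosis: Prior ADHF.\nBrief Hospital Course: Stable."),
    clinical_note("n4", "adm_ruleout", "2010-03-04T09:00:00",
      "Chief Complaint: Dyspnea.\nBrief Hospital Course: Rule out ADHF."),
    clinical_note("n5", "adm_negative_for", "2010-03-05T09:00:00",
      "Principal Diagnosis: Negative for ADHF on echo.\nBrief Hospital Course: Improved."),
    clinical_note("n6", "adm_mixed", "2010-03-06T09:00:00",
      "Brief Hospital Course: Negative for ADHF initially. Admitted for ADHF exacerbation.")
  )
}

fixture_dictionary <- function(...) {
  term_dictionary(
    inclusion_terms = c("acute decompensated heart failure", "adhf"),
    exclusion_terms = c("prior", "rule out", "negative for"),
    scoped_sections = c("principal_diagnosis", "secondary_diagnoses",
                        "chief_complaint", "brief_hospital_course"),
    ...
  )
}

# small random word pool for adversarial corpora; includes fragments of the
# dictionary phrases so boundary handling is exercised
fixture_word_pool <- c(
  "the", "patient", "acute", "chf", "heart", "failure", "decompensated",
  "adhf", "badhfx", "prior", "rule", "out", "negative", "for", "stable",
  "pneumonia", "edema", "exacerbation", "12.5", "mg"
)

random_note_text <- function(pool = fixture_word_pool) {
  render_sentence <- function() {
    words <- sample(pool, sample(3:9, 1), replace = TRUE)
    words <- vapply(words, function(w) {
      if (stats::runif(1) < 0.3) toupper(w) else w
    }, character(1))
    paste0(paste(words, collapse = if (stats::runif(1) < 0.2) "  " else " "),
           sample(c(".", ";", "?", "!"), 1))
  }
  sections <- c("Principal Diagnosis", "Secondary Diagnoses",
                "Chief Complaint", "Brief Hospital Course", "Family History")
  picked <- sample(sections, sample(2:5, 1))
  paste0(vapply(picked, function(s) {
    body <- paste(replicate(sample(1:3, 1), render_sentence()), collapse = " ")
    paste0(s, ": ", body, "\n")
  }, character(1)), collapse = "")
}

random_corpus <- function(n_notes, n_admissions = max(1L, n_notes %/% 2L)) {
  adm <- sprintf("A%03d", sample.int(n_admissions, n_notes, replace = TRUE))
  lapply(seq_len(n_notes), function(i) {
    clinical_note(sprintf("N%03d", i), adm[i], "2010-01-01T00:00:00",
                  random_note_text())
  })
}
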