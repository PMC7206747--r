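#' Specify a synthetic EHR cohort
#'
#' Parameters of the seeded generator that emulates the data regime the
#' phenotype was derived and validated in: hospital admissions with
#' sectioned notes, an imperfect ICD-9 coding process, and ground-truth
#' ADHF labels recorded before any text is rendered.
#'
#' The defaults encode that regime: ADHF prevalence 0.40 among reviewed
#' admissions; a true case is documented with an affirmed surface form in a
#' scoped section with probability 0.975 (text documentation is nearly
#' complete, which is what makes a free-text search competitive); an acute
#' 428.x1/x3 code is assigned to 47.5% of true cases while some 428-family
#' code is assigned to 97.5% of cases and 13.3% of controls (coding is
#' sensitive for heart failure generally but poor at marking acuity); 15%
#' of true negatives carry a negated or historical mention, and 5% of
#' otherwise-undocumented mentions land only in a non-scoped section.
#' Minor and unauthorized fractions mirror the eligibility funnel
#' (44,867/314,988 and 13,678/270,121).
#'
#' @param n_patients Number of patients (one admission per patient unless
#'   `max_admissions_per_patient > 1`).
#' @param prevalence Probability an admission is a true ADHF case.
#' @param p_document Probability a true case is documented with an affirmed
#'   inclusion surface form in a scoped section.
#' @param p_negated_mention Probability a true-negative admission carries a
#'   negated/historical mention in a scoped section.
#' @param p_out_of_scope_mention Probability an otherwise-unmentioned
#'   admission gets a mention only in a non-scoped section (family history).
#' @param p_acute_code_given_case Probability a true case receives an acute
#'   heart-failure ICD-9 code.
#' @param p_anyhf_code_given_case Probability a true case receives any
#'   428-family code (an acute code implies one; must be >=
#'   `p_acute_code_given_case`).
#' @param p_anyhf_code_given_control Probability a control receives a
#'   (chronic) 428-family code.
#' @param minor_fraction,unauthorized_fraction Probabilities a patient is
#'   under 18 at admission, resp. lacks research authorization.
#' @param max_admissions_per_patient Upper bound on admissions per patient
#'   (default 1: admission-level detection, one admission each).
#' @param seed Integer seed; every random draw in [generate_cohort()] flows
#'   from it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 500L,
                        prevalence = 0.40,
                        p_document = 0.975,
                        p_negated_mention = 0.15,
                        p_out_of_scope_mention = 0.05,
                        p_acute_code_given_case = 0.475,
                        p_anyhf_code_given_case = 0.975,
                        p_anyhf_code_given_control = 0.133,
                        minor_fraction = 44867 / 314988,
                        unauthorized_fraction = 13678 / 270121,
                        max_admissions_per_patient = 1L,
                        seed = 1L) {
  probs <- c(prevalence = prevalence, p_document = p_document,
             p_negated_mention = p_negated_mention,
             p_out_of_scope_mention = p_out_of_scope_mention,
             p_acute_code_given_case = p_acute_code_given_case,
             p_anyhf_code_given_case = p_anyhf_code_given_case,
             p_anyhf_code_given_control = p_anyhf_code_given_control,
             minor_fraction = minor_fraction,
             unauthorized_fraction = unauthorized_fraction)
  bad <- names(probs)[probs < 0 | probs > 1 | is.na(probs)]
  if (length(bad)) {
    stop("probability field(s) outside [0, 1]: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (p_anyhf_code_given_case < p_acute_code_given_case) {
    stop("p_anyhf_code_given_case must be >= p_acute_code_given_case ",
         "(an acute code is a 428-family code)", call. = FALSE)
  }
  if (!is.numeric(n_patients) || n_patients < 1) {
    stop("n_patients must be >= 1", call. = FALSE)
  }
  if (max_admissions_per_patient < 1) {
    stop("max_admissions_per_patient must be >= 1", call. = FALSE)
  }
  structure(
    list(n_patients = as.integer(n_patients), prevalence = prevalence,
         p_document = p_document, p_negated_mention = p_negated_mention,
         p_out_of_scope_mention = p_out_of_scope_mention,
         p_acute_code_given_case = p_acute_code_given_case,
         p_anyhf_code_given_case = p_anyhf_code_given_case,
         p_anyhf_code_given_control = p_anyhf_code_given_control,
         minor_fraction = minor_fraction,
         unauthorized_fraction = unauthorized_fraction,
         max_admissions_per_patient = as.integer(max_admissions_per_patient),
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec> ", x$n_patients, " patients, prevalence ", x$prevalence,
      ", p_document ", x$p_document, ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# --- generator vocabulary ---------------------------------------------------
# Surface forms, cues, sections and templates are fixed module-level data:
# they are part of the generator's declared manifest, which tests use to
# build matched or deliberately impoverished dictionaries.

synth_surface_forms <- function() {
  c("acute decompensated heart failure",
    "decompensated heart failure",
    "acute on chronic systolic heart failure",
    "acute diastolic heart failure",
    "heart failure exacerbation",
    "adhf")
}

synth_negation_cues <- function() c("prior", "rule out", "negative for")

synth_templates <- function() {
  list(
    affirm = list(
      chief_complaint = c(
        "Dyspnea and weight gain concerning for %s.",
        "Worsening shortness of breath due to %s.",
        "Volume overload from %s."),
      principal_diagnosis = c(
        "%s.",
        "%s with volume overload.",
        "%s requiring iv diuresis."),
      secondary_diagnoses = c(
        "Atrial fibrillation. %s. Stage 3 chronic kidney disease.",
        "%s. Hypertension.",
        "Type 2 diabetes mellitus. %s."),
      brief_hospital_course = c(
        "The patient was admitted with %s and diuresed with improvement.",
        "Treated for %s with iv furosemide and daily weights.",
        "Course notable for %s managed medically.")
    ),
    negate = c(
      "%s.",
      "Assessment notable for %s.",
      "Admission workup: %s at this time."),
    base = list(
      chief_complaint = c(
        "Chest pain.", "Fever and productive cough.", "Generalized weakness."),
      principal_diagnosis = c(
        "Community acquired pneumonia.",
        "Urinary tract infection.",
        "Non st elevation myocardial infarction."),
      secondary_diagnoses = c(
        "Hypertension. Hyperlipidemia.",
        "Atrial fibrillation. Anemia.",
        "Stage 3 chronic kidney disease."),
      brief_hospital_course = c(
        "The patient improved with antibiotics and was discharged home.",
        "Symptoms improved with supportive care.",
        "An uneventful course; discharged in stable condition.")
    ),
    family_history = c(
      "Mother with %s.",
      "Family history includes %s in a sibling.",
      "Father had %s."),
    family_history_base = c(
      "No significant family history.",
      "Family history of hypertension.",
      "Family history noncontributory."),
    medications = c(
      "Lisinopril, metoprolol, atorvastatin.",
      "Furosemide, carvedilol, aspirin.",
      "Metformin, amlodipine.")
  )
}

synth_acute_codes <- function() {
  c("428.21", "428.23", "428.31", "428.33", "428.41", "428.43")
}
synth_chronic_hf_codes <- function() {
  c("428.0", "428.22", "428.32", "428.42", "428.9")
}
synth_distractor_codes <- function() {
  c("401.9", "250.00", "414.01", "486", "584.9", "599.0", "272.4")
}

#' Describe what the generator can emit
#'
#' A machine-readable manifest of the generator's vocabulary: the inclusion
#' surface forms it documents true cases with, the negation cues it renders
#' before a form in true-negative admissions, the scoped sections mentions
#' are placed in, the distractor sections, and the ICD-9 code pools. Tests
#' and the refinement workflow use it to build a matched dictionary
#' ([matched_dictionary()]) or a deliberately impoverished one.
#'
#' @param spec A [cohort_spec()] (the manifest is currently
#'   spec-independent but is keyed to one for forward compatibility).
#' @return A list with elements `surface_forms`, `negation_cues`,
#'   `scoped_sections`, `distractor_sections`, `acute_codes`,
#'   `chronic_hf_codes`, `distractor_codes`.
#' @export
generator_manifest <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  list(
    surface_forms = synth_surface_forms(),
    negation_cues = synth_negation_cues(),
    scoped_sections = default_scoped_sections(),
    distractor_sections = c("family_history", "medications"),
    acute_codes = synth_acute_codes(),
    chronic_hf_codes = synth_chronic_hf_codes(),
    distractor_codes = synth_distractor_codes()
  )
}

#' Build the dictionary matched to the generator
#'
#' @param manifest Output of [generator_manifest()].
#' @param with_exclusions Include the generator's negation cues as
#'   exclusion terms? Default `TRUE`.
#' @param drop_forms Surface forms to leave out (for building deliberately
#'   impoverished dictionaries in refinement experiments).
#' @return A [term_dictionary()].
#' @export
matched_dictionary <- function(manifest = generator_manifest(),
                               with_exclusions = TRUE,
                               drop_forms = character(0)) {
  forms <- setdiff(manifest$surface_forms, drop_forms)
  term_dictionary(
    inclusion_terms = forms,
    exclusion_terms = if (with_exclusions) manifest$negation_cues
                      else character(0),
    scoped_sections = manifest$scoped_sections
  )
}

#' Generate a synthetic EHR cohort
#'
#' Draws, per admission: the ground-truth ADHF label (before any text is
#' rendered), the documentation arm (affirmed mention in a uniformly chosen
#' scoped section, negated/historical mention, out-of-scope mention, or
#' none), the ICD-9 codes (acute and/or chronic 428-family codes per the
#' coding model, plus distractor codes), and a sectioned discharge note
#' assembled from templates and segmented with [segment_note()]. Patients
#' get a birth date and research-authorization flag per the eligibility
#' fractions. Everything is reproducible from `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @return A list with elements `patients` (tibble: `patient_id`,
#'   `birth_date`, `research_authorization`), `admissions` (tibble:
#'   `admission_id`, `patient_id`, `admit_date`, `discharge_date`,
#'   list-column `icd9_codes`), `notes` (list of [clinical_note]), `truth`
#'   (tibble: `admission_id`, `adhf`, `mention_kind`, `source =
#'   "synthetic_truth"`), and `manifest` ([generator_manifest()]).
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  manifest <- generator_manifest(spec)
  tpl <- synth_templates()
  withr::with_seed(spec$seed, {
    np <- spec$n_patients
    patient_id <- sprintf("P%05d", seq_len(np))
    minor <- stats::runif(np) < spec$minor_fraction
    unauthorized <- stats::runif(np) < spec$unauthorized_fraction

    n_adm_per <- if (spec$max_admissions_per_patient == 1L) {
      rep(1L, np)
    } else {
      sample.int(spec$max_admissions_per_patient, np, replace = TRUE)
    }
    na <- sum(n_adm_per)
    adm_patient <- rep(patient_id, n_adm_per)
    admission_id <- sprintf("A%05d", seq_len(na))

    # admissions fall in the 2006-2014 study window
    window_start <- as.Date("2006-01-01")
    admit_date <- window_start + sample.int(3200L, na, replace = TRUE) - 1L
    discharge_date <- admit_date + sample.int(13L, na, replace = TRUE)

    # birth dates put minors at ~10y and adults at 30-90y on first admission
    first_admit <- as.Date(
      tapply(as.numeric(admit_date), adm_patient, min)[patient_id],
      origin = "1970-01-01")
    age_years <- ifelse(minor, stats::runif(np, 4, 16),
                        stats::runif(np, 30, 90))
    birth_date <- first_admit - round(age_years * 365.25)

    # --- ground truth, drawn before any note text is rendered ---
    adhf <- stats::runif(na) < spec$prevalence
    u_doc <- stats::runif(na)
    u_oos <- stats::runif(na)
    mention_kind <- rep("none", na)
    mention_kind[adhf & u_doc < spec$p_document] <- "affirmed"
    mention_kind[adhf & u_doc >= spec$p_document &
                   u_oos < spec$p_out_of_scope_mention] <- "out_of_scope"
    neg <- !adhf & u_doc < spec$p_negated_mention
    cue <- rep(NA_character_, na)
    cue[neg] <- sample(manifest$negation_cues, sum(neg), replace = TRUE)
    mention_kind[neg] <- ifelse(cue[neg] == "prior", "historical", "negated")
    mention_kind[!adhf & !neg & u_oos < spec$p_out_of_scope_mention] <-
      "out_of_scope"

    form <- sample(manifest$surface_forms, na, replace = TRUE)
    scoped <- manifest$scoped_sections
    target_section <- sample(scoped, na, replace = TRUE)

    # --- ICD-9 codes ---
    has_acute <- adhf & stats::runif(na) < spec$p_acute_code_given_case
    p_chronic_extra <- if (spec$p_acute_code_given_case < 1) {
      (spec$p_anyhf_code_given_case - spec$p_acute_code_given_case) /
        (1 - spec$p_acute_code_given_case)
    } else 0
    has_chronic <- (adhf & !has_acute & stats::runif(na) < p_chronic_extra) |
      (!adhf & stats::runif(na) < spec$p_anyhf_code_given_control)
    acute_code <- sample(manifest$acute_codes, na, replace = TRUE)
    chronic_code <- sample(manifest$chronic_hf_codes, na, replace = TRUE)
    n_distract <- sample.int(3L, na, replace = TRUE) - 1L
    icd9_codes <- lapply(seq_len(na), function(i) {
      cs <- character(0)
      if (has_acute[i]) cs <- c(cs, acute_code[i])
      if (has_chronic[i]) cs <- c(cs, chronic_code[i])
      if (n_distract[i] > 0L) {
        cs <- c(cs, sample(manifest$distractor_codes, n_distract[i]))
      }
      unique(cs)
    })

    # --- note text ---
    pick <- function(templates, k) templates[sample.int(length(templates), k,
                                                        replace = TRUE)]
    notes <- vector("list", na)
    for (i in seq_len(na)) {
      body <- list()
      for (sec in scoped) {
        sentence <- pick(tpl$base[[sec]], 1L)
        if (sec == target_section[i]) {
          if (mention_kind[i] == "affirmed") {
            sentence <- sprintf(pick(tpl$affirm[[sec]], 1L), form[i])
          } else if (mention_kind[i] %in% c("negated", "historical")) {
            sentence <- sprintf(pick(tpl$negate, 1L),
                                paste(cue[i], form[i]))
          }
        }
        body[[sec]] <- sentence
      }
      fh <- if (mention_kind[i] == "out_of_scope") {
        sprintf(pick(tpl$family_history, 1L), form[i])
      } else {
        pick(tpl$family_history_base, 1L)
      }
      text <- paste0(
        "Chief Complaint/Reason for Visit: ", body$chief_complaint, "\n",
        "Principal Diagnosis: ", body$principal_diagnosis, "\n",
        "Secondary Diagnoses: ", body$secondary_diagnoses, "\n",
        "Brief Hospital Course: ", body$brief_hospital_course, "\n",
        "Family History: ", fh, "\n",
        "Medications: ", pick(tpl$medications, 1L), "\n")
      notes[[i]] <- clinical_note(
        note_id = sprintf("N%05d", i),
        admission_id = admission_id[i],
        patient_id = adm_patient[i],
        timestamp = paste0(format(admit_date[i], "%Y-%m-%d"), "T08:00:00"),
        text = text
      )
    }

    list(
      patients = tibble::tibble(
        patient_id = patient_id,
        birth_date = birth_date,
        research_authorization = !unauthorized
      ),
      admissions = tibble::tibble(
        admission_id = admission_id,
        patient_id = adm_patient,
        admit_date = admit_date,
        discharge_date = discharge_date,
        icd9_codes = icd9_codes
      ),
      notes = notes,
      truth = tibble::tibble(
        admission_id = admission_id,
        adhf = adhf,
        mention_kind = mention_kind,
        source = "synthetic_truth"
      ),
      manifest = manifest
    )
  })
}

#' Named reference-label vector from a truth table
#'
#' @param truth The `truth` tibble from [generate_cohort()] or the tibble
#'   returned by [read_reference_labels()].
#' @return Named logical vector keyed by admission id.
#' @export
reference_vector <- function(truth) {
  stats::setNames(truth$adhf, truth$admission_id)
}

#' Write a generated cohort to a directory
#'
#' Emits the interchange files the CLI and protocol runner consume:
#' `notes.jsonl`, `codes.csv`, `labels.csv` (source `synthetic_truth`),
#' `patients.csv`, `admissions.csv` and `manifest.json`.
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_note_corpus(cohort$notes, file.path(dir, "notes.jsonl"))
  write_icd9_codes(cohort$admissions, file.path(dir, "codes.csv"))
  write_reference_labels(cohort$truth, file.path(dir, "labels.csv"))
  utils::write.csv(
    data.frame(patient_id = cohort$patients$patient_id,
               birth_date = format(cohort$patients$birth_date),
               research_authorization =
                 as.integer(cohort$patients$research_authorization)),
    file.path(dir, "patients.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(admission_id = cohort$admissions$admission_id,
               patient_id = cohort$admissions$patient_id,
               admit_date = format(cohort$admissions$admit_date),
               discharge_date = format(cohort$admissions$discharge_date)),
    file.path(dir, "admissions.csv"), row.names = FALSE)
  jsonlite::write_json(cohort$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
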