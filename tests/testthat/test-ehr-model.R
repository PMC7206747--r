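test_that("note segmentation finds headers and assigns bodies", {
  s <- segment_note("Principal Diagnosis: ADHF\nBrief Hospital Course: improved")
  expect_identical(s$name, c("principal_diagnosis", "brief_hospital_course"))
  raw <- "Principal Diagnosis: ADHF\nBrief Hospital Course: improved"
  expect_identical(substring(raw, s$start + 1L, s$end),
                   c("ADHF\n", "improved"))

  expect_identical(nrow(segment_note("")), 0L)

  s2 <- segment_note("free text with no recognized header at all")
  expect_identical(s2$name, "preamble")
  expect_identical(c(s2$start, s2$end),
                   c(0L, nchar("free text with no recognized header at all")))
})

test_that("segmentation is case-insensitive, offset-sound and keeps preambles", {
  raw <- paste0("Transfer note.\nCHIEF COMPLAINT/REASON FOR VISIT: dyspnea\n",
                "secondary diagnoses - CKD\nMedications: lasix")
  s <- segment_note(raw)
  expect_identical(s$name, c("preamble", "chief_complaint",
                             "secondary_diagnoses", "medications"))
  expect_true(all(s$start >= 0 & s$end <= nchar(raw) & s$start <= s$end))
  # spans are non-overlapping and ordered
  expect_true(all(s$start[-1] >= s$end[-nrow(s)]))
  expect_identical(trimws(substring(raw, s$start[1] + 1, s$end[1])),
                   "Transfer note.")
})

test_that("corpus writing and reading round-trips exactly", {
  notes <- fixture_notes()
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_note_corpus(notes, path)
  back <- read_note_corpus(path)
  expect_length(back, length(notes))
  for (i in seq_along(notes)) {
    expect_identical(back[[i]]$note_id, notes[[i]]$note_id)
    expect_identical(back[[i]]$admission_id, notes[[i]]$admission_id)
    expect_identical(back[[i]]$text, notes[[i]]$text)
    expect_identical(back[[i]]$sections$name, notes[[i]]$sections$name)
    expect_identical(back[[i]]$sections$start, notes[[i]]$sections$start)
    expect_identical(back[[i]]$sections$end, notes[[i]]$sections$end)
    expect_equal(back[[i]]$timestamp, notes[[i]]$timestamp)
  }
})

test_that("corpus reader reports malformed and duplicate records by line", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c(
    '{"note_id":"a","admission_id":"x","timestamp":"2010-01-01T00:00:00","text":"Principal Diagnosis: ok"}',
    '{"note_id":"b","timestamp":"2010-01-01T00:00:00","text":"no admission"}'
  ), path)
  expect_error(read_note_corpus(path), "line 2.*admission_id")

  writeLines(character(0), path)
  expect_identical(read_note_corpus(path), list())

  writeLines(c(
    '{"note_id":"a","admission_id":"x","timestamp":"2010-01-01T00:00:00","text":"t"}',
    '{"note_id":"a","admission_id":"y","timestamp":"2010-01-01T00:00:00","text":"t"}'
  ), path)
  expect_error(read_note_corpus(path), "line 2.*duplicate note_id")

  writeLines("{not json", path)
  expect_error(read_note_corpus(path), "line 1.*malformed")
})

test_that("eligibility filter partitions exclusions as in the study funnel", {
  # 10 patients: 3 minors, 2 unauthorized adults -> 5 eligible
  patients <- tibble::tibble(
    patient_id = sprintf("P%02d", 1:10),
    birth_date = as.Date(c("2000-06-01", "1999-01-01", "1995-12-31",  # minors
                           "1950-01-01", "1960-01-01",                # unauth
                           "1940-01-01", "1970-01-01", "1980-01-01",
                           "1985-01-01", "1930-01-01")),
    research_authorization = c(TRUE, TRUE, FALSE,
                               FALSE, FALSE,
                               TRUE, TRUE, TRUE, TRUE, TRUE)
  )
  admissions <- tibble::tibble(
    admission_id = sprintf("A%02d", 1:10),
    patient_id = patients$patient_id,
    admit_date = as.Date("2010-06-15")
  )
  res <- filter_eligible(patients, admissions)
  expect_identical(res$flow$n_excluded_age, 3L)   # P03 is a minor AND unauth:
  expect_identical(res$flow$n_excluded_auth, 2L)  # counted in the age arm
  expect_identical(res$flow$n_eligible, 5L)
  expect_setequal(res$eligible$patient_id,
                  c("P06", "P07", "P08", "P09", "P10"))
  # conservation
  expect_identical(res$flow$n_eligible + res$flow$n_excluded_age +
                     res$flow$n_excluded_auth, res$flow$n_patients)

  # all adult + authorized -> nobody excluded
  ok <- patients
  ok$birth_date <- as.Date("1950-01-01")
  ok$research_authorization <- TRUE
  expect_identical(filter_eligible(ok, admissions)$flow$n_eligible, 10L)

  bad <- admissions
  bad$patient_id[1] <- "ghost"
  expect_error(filter_eligible(patients, bad), "unknown patient")
})

test_that("age is whole years at the first admission", {
  patients <- tibble::tibble(
    patient_id = c("a", "b"),
    birth_date = as.Date(c("1992-06-16", "1992-06-15")),
    research_authorization = TRUE
  )
  admissions <- tibble::tibble(
    admission_id = c("x", "y"),
    patient_id = c("a", "b"),
    admit_date = as.Date("2010-06-15")  # day before vs on 18th birthday
  )
  res <- filter_eligible(patients, admissions)
  expect_identical(res$eligible$patient_id, "b")
})

test_that("cohort flow arithmetic holds and rejects impossible counts", {
  flow <- cohort_flow(473146, 314988, 44867, 13678)
  expect_identical(flow$n_eligible, 256443L)
  expect_error(cohort_flow(10, 5, 4, 3), "exceed")
  expect_error(cohort_flow(10, -1, 0, 0), "non-negative")
})

test_that("code lists and reference labels round-trip through CSV", {
  adm <- tibble::tibble(
    admission_id = c("a1", "a2", "a3"),
    icd9_codes = list(c("428.21", "401.9"), character(0), "428.0")
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_icd9_codes(adm, path)
  back <- read_icd9_codes(path)
  expect_identical(back$admission_id, c("a1", "a3"))  # a2 has no codes
  expect_identical(back$icd9_codes[[1]], c("428.21", "401.9"))

  labels <- tibble::tibble(admission_id = c("a1", "a2"),
                           adhf = c(TRUE, FALSE),
                           source = "synthetic_truth")
  lpath <- withr::local_tempfile(fileext = ".csv")
  write_reference_labels(labels, lpath)
  expect_identical(read_reference_labels(lpath), labels)

  writeLines("admission_id,adhf,source\nz,1,manual_review\nz,0,manual_review",
             lpath)
  expect_error(read_reference_labels(lpath), "duplicate")
})
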