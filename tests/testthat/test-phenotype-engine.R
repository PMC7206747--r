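test_that("inclusion matching respects boundaries and longest-match order", {
  d <- fixture_dictionary()
  m <- find_inclusion_matches(
    "acute decompensated heart failure with edema", d, "principal_diagnosis")
  expect_identical(nrow(m), 1L)
  expect_identical(m$term, "acute decompensated heart failure")

  expect_identical(nrow(find_inclusion_matches("BADHFX", d)), 0L)
  expect_identical(nrow(find_inclusion_matches("adhf. adhf.", d)), 2L)

  # the long phrase wins over its embedded abbreviation-free overlap; the
  # scanner does not double-count inside the consumed span
  d2 <- term_dictionary(c("heart failure", "acute heart failure"))
  m2 <- find_inclusion_matches("acute heart failure", d2)
  expect_identical(m2$term, "acute heart failure")
})

test_that("match offsets index the original section text", {
  d <- fixture_dictionary()
  txt <- "Likely  Acute   Decompensated\nHeart Failure; prior ADHF noted"
  m <- find_inclusion_matches(txt, d, "principal_diagnosis")
  expect_identical(nrow(m), 2L)
  for (i in seq_len(nrow(m))) {
    span <- substr(txt, m$start[i] + 1L, m$end[i])
    norm_span <- tolower(gsub("[[:space:]]+", " ", span))
    expect_identical(norm_span, m$term[i])
  }
})

test_that("each printed exclusion cue suppresses a hit in its sentence", {
  d <- fixture_dictionary()
  cases <- list(
    list(text = "rule out ADHF", cue = "rule out"),
    list(text = "Prior ADHF.", cue = "prior"),
    list(text = "negative for ADHF today", cue = "negative for")
  )
  for (cs in cases) {
    m <- find_inclusion_matches(cs$text, d, "principal_diagnosis")
    m <- apply_exclusions(m, cs$text, d)
    expect_identical(m$suppressed_by, cs$cue)
  }
})

test_that("sentence scoping confines suppression to the cue's sentence", {
  d <- fixture_dictionary()
  txt <- "negative for ADHF. Admitted for ADHF exacerbation."
  m <- apply_exclusions(find_inclusion_matches(txt, d, "x"), txt, d)
  expect_identical(m$suppressed_by, c("negative for", NA))

  # no exclusion phrases present -> identity
  txt2 <- "Admitted for ADHF."
  m2 <- find_inclusion_matches(txt2, d, "x")
  expect_identical(apply_exclusions(m2, txt2, d), m2)
})

test_that("window scoping counts tokens, not sentences", {
  dw <- fixture_dictionary(exclusion_scope = "window", window_tokens = 3L)
  txt <- "rule out for now ADHF"           # cue 3 tokens before the match
  m <- apply_exclusions(find_inclusion_matches(txt, dw, "x"), txt, dw)
  expect_identical(m$suppressed_by, "rule out")

  txt2 <- "rule out one two three four ADHF"  # cue beyond the window
  m2 <- apply_exclusions(find_inclusion_matches(txt2, dw, "x"), txt2, dw)
  expect_true(is.na(m2$suppressed_by))

  txt3 <- "ADHF then rule out"            # cue after the match never fires
  m3 <- apply_exclusions(find_inclusion_matches(txt3, dw, "x"), txt3, dw)
  expect_true(is.na(m3$suppressed_by))
})

test_that("admission classification scopes sections and aggregates notes", {
  d <- fixture_dictionary()
  notes <- fixture_notes()
  by_adm <- split(notes, vapply(notes, function(x) x$admission_id, character(1)))

  expect_true(classify_admission(by_adm$adm_pos, d)$adhf)
  expect_false(classify_admission(by_adm$adm_neg_section, d)$adhf)
  expect_false(classify_admission(by_adm$adm_prior, d)$adhf)
  expect_false(classify_admission(by_adm$adm_ruleout, d)$adhf)
  expect_false(classify_admission(by_adm$adm_negative_for, d)$adhf)

  v <- classify_admission(by_adm$adm_mixed, d)
  expect_true(v$adhf)
  expect_identical(nrow(v$kept_matches), 1L)
  expect_identical(v$suppressed_matches$suppressed_by, "negative for")

  empty <- classify_admission(list(), d, admission_id = "none")
  expect_false(empty$adhf)
  expect_identical(nrow(empty$kept_matches), 0L)
})

test_that("verdicts are positive iff a kept match exists", {
  d <- fixture_dictionary()
  res <- run_phenotype(fixture_notes(), d)
  expect_length(res, 6L)
  for (v in res) expect_identical(v$adhf, nrow(v$kept_matches) > 0L)
  tab <- verdict_table(res)
  expect_identical(tab$adhf, unname(verdict_predictions(res)[tab$admission_id]))
  expect_length(run_phenotype(list(), d), 0L)
})

test_that("verdicts are independent of note order in the corpus", {
  withr::local_seed(11)
  notes <- random_corpus(30)
  d <- fixture_dictionary()
  res1 <- run_phenotype(notes, d)
  res2 <- run_phenotype(rev(notes), d)
  expect_identical(verdict_predictions(res1), verdict_predictions(res2))
  expect_identical(verdict_table(res1), verdict_table(res2))
})

test_that("growing the dictionary moves verdicts monotonically", {
  withr::local_seed(23)
  notes <- random_corpus(40)
  base <- term_dictionary(c("adhf", "acute chf"), c("prior"),
                          scoped_sections = default_scoped_sections())
  wider <- term_dictionary(c("adhf", "acute chf", "decompensated"),
                           c("prior"),
                           scoped_sections = default_scoped_sections())
  stricter <- term_dictionary(c("adhf", "acute chf"),
                              c("prior", "rule out", "negative for"),
                              scoped_sections = default_scoped_sections())
  p_base <- verdict_predictions(run_phenotype(notes, base))
  p_wider <- verdict_predictions(run_phenotype(notes, wider))
  p_strict <- verdict_predictions(run_phenotype(notes, stricter))
  # adding inclusion terms never flips positive -> negative
  expect_true(all(p_wider[p_base]))
  # adding exclusion terms never flips negative -> positive
  expect_true(all(!p_strict[!p_base]))
})

test_that("text outside scoped sections never contributes evidence", {
  d <- fixture_dictionary()
  note <- clinical_note("n", "a", "2010-01-01T00:00:00",
    "Family History: ADHF in mother.\nMedications: lasix.\nPast Medical History: adhf")
  v <- classify_admission(list(note), d)
  expect_false(v$adhf)
  expect_identical(nrow(v$kept_matches), 0L)
  expect_identical(nrow(v$suppressed_matches), 0L)
})

test_that("engine verdicts equal the brute-force oracle on random corpora", {
  withr::local_seed(307)
  d_default <- fixture_dictionary()
  for (rep in 1:25) {
    notes <- random_corpus(sample(5:30, 1))
    engine <- verdict_predictions(run_phenotype(notes, d_default))
    oracle <- oracle_classify_corpus(notes, d_default)
    expect_identical(engine, oracle)
  }
})
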