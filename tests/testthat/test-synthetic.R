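test_that("the same seed reproduces the cohort byte-for-byte", {
  spec <- cohort_spec(n_patients = 60, seed = 42)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1$patients, c2$patients)
  expect_identical(c1$admissions, c2$admissions)
  expect_identical(c1$truth, c2$truth)
  expect_identical(lapply(c1$notes, `[[`, "text"),
                   lapply(c2$notes, `[[`, "text"))

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(c1, d1); write_cohort(c2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }

  c3 <- generate_cohort(cohort_spec(n_patients = 60, seed = 43))
  expect_false(identical(lapply(c1$notes, `[[`, "text"),
                         lapply(c3$notes, `[[`, "text")))
})

test_that("spec validation names the offending field", {
  expect_error(cohort_spec(prevalence = 1.2), "prevalence")
  expect_error(cohort_spec(p_document = -0.1), "p_document")
  expect_error(cohort_spec(n_patients = 0), "n_patients")
  expect_error(cohort_spec(p_acute_code_given_case = 0.9,
                           p_anyhf_code_given_case = 0.5),
               "p_anyhf_code_given_case")
})

test_that("the manifest declares the vocabulary tests build dictionaries from", {
  man <- generator_manifest()
  expect_gte(length(man$surface_forms), 5L)
  expect_identical(man$negation_cues, c("prior", "rule out", "negative for"))
  expect_setequal(man$scoped_sections, default_scoped_sections())

  d <- matched_dictionary(man)
  expect_true(all(man$surface_forms %in% d$inclusion_terms))
  d_poor <- matched_dictionary(man, drop_forms = man$surface_forms[1:2])
  expect_length(d_poor$inclusion_terms, length(man$surface_forms) - 2L)
})

test_that("rendered notes are consistent with the recorded truth", {
  co <- generate_cohort(cohort_spec(n_patients = 300, seed = 99))
  d <- matched_dictionary(co$manifest)
  res <- run_phenotype(co$notes, d)
  pred <- verdict_predictions(res)
  truth <- co$truth

  # every admission the engine calls positive is a true case: negated
  # mentions are suppressed and out-of-scope mentions never match
  expect_true(all(truth$adhf[match(names(pred)[pred], truth$admission_id)]))

  # every affirmed-documented case is found
  affirmed <- truth$admission_id[truth$mention_kind == "affirmed"]
  expect_true(all(pred[affirmed]))

  # negated/historical mentions leave suppressed-match evidence
  negated <- truth$admission_id[truth$mention_kind %in% c("negated", "historical")]
  n_supp <- vapply(res[negated], function(v) nrow(v$suppressed_matches),
                   integer(1))
  expect_true(all(n_supp >= 1L))

  # mention kinds respect the documentation model
  expect_true(all(truth$mention_kind[truth$adhf] %in%
                    c("affirmed", "out_of_scope", "none")))
})

test_that("noiseless generation yields perfect text recovery", {
  spec <- cohort_spec(n_patients = 120, prevalence = 0.4, p_document = 1,
                      p_negated_mention = 0, p_out_of_scope_mention = 0,
                      seed = 7)
  co <- generate_cohort(spec)
  pred <- verdict_predictions(run_phenotype(co$notes, matched_dictionary()))
  expect_identical(pred[co$truth$admission_id], reference_vector(co$truth))
})

test_that("empirical arm frequencies converge to the spec probabilities", {
  spec <- cohort_spec(n_patients = 5000, seed = 2024)
  co <- generate_cohort(spec)
  truth <- co$truth
  n <- nrow(truth)

  within_3se <- function(p_hat, p, m) {
    se <- sqrt(p * (1 - p) / m)
    abs(p_hat - p) <= 3 * se + 1e-9
  }

  # prevalence
  expect_true(within_3se(mean(truth$adhf), spec$prevalence, n))

  # documentation probability among cases
  cases <- truth[truth$adhf, ]
  expect_true(within_3se(mean(cases$mention_kind == "affirmed"),
                         spec$p_document, nrow(cases)))

  # negated-mention probability among controls
  controls <- truth[!truth$adhf, ]
  expect_true(within_3se(
    mean(controls$mention_kind %in% c("negated", "historical")),
    spec$p_negated_mention, nrow(controls)))

  # coding model
  acute <- run_code_strategy(co$admissions, acute_hf_codes())
  all_hf <- run_code_strategy(co$admissions, all_hf_codes())
  case_ids <- cases$admission_id
  ctrl_ids <- controls$admission_id
  expect_true(within_3se(mean(acute[case_ids]),
                         spec$p_acute_code_given_case, length(case_ids)))
  expect_true(within_3se(mean(all_hf[case_ids]),
                         spec$p_anyhf_code_given_case, length(case_ids)))
  expect_true(within_3se(mean(all_hf[ctrl_ids]),
                         spec$p_anyhf_code_given_control, length(ctrl_ids)))

  # an acute code is always a heart-failure code
  expect_true(all(all_hf[acute]))

  # eligibility fractions, via the cohort filter itself
  flow <- filter_eligible(co$patients, co$admissions)$flow
  expect_true(within_3se(flow$n_excluded_age / flow$n_patients,
                         spec$minor_fraction, flow$n_patients))
  n_adult <- flow$n_patients - flow$n_excluded_age
  expect_true(within_3se(flow$n_excluded_auth / n_adult,
                         spec$unauthorized_fraction, n_adult))
})
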