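test_that("confusion matrix counts cells against the reference", {
  ids <- sprintf("a%02d", 1:10)
  ref <- stats::setNames(c(rep(TRUE, 4), rep(FALSE, 6)), ids)
  tt <- confusion_matrix(ref, ref)
  expect_identical(c(tt$tp, tt$fp, tt$fn, tt$tn), c(4L, 0L, 0L, 6L))
  expect_identical(tt$n, 10L)

  ref8 <- stats::setNames(c(TRUE, TRUE, TRUE, rep(FALSE, 5)),
                          sprintf("b%d", 1:8))
  none <- stats::setNames(rep(FALSE, 8), names(ref8))
  tt2 <- confusion_matrix(none, ref8)
  expect_identical(c(tt2$tp, tt2$fp, tt2$fn, tt2$tn), c(0L, 0L, 3L, 5L))

  # reference admissions without predictions are an error naming ids
  expect_error(confusion_matrix(none[1:4], ref8), "b5")
  # predictions without labels are ignored with a message, and counted
  extra <- c(none, z9 = TRUE)
  expect_message(tt3 <- confusion_matrix(extra, ref8), "1 prediction")
  expect_identical(tt3$n, 8L)
  expect_identical(tt3$n_unlabelled, 1L)
})

test_that("sensitivity and specificity evaluate their defining ratios", {
  expect_equal(sensitivity(two_by_two(39, 0, 1, 60))$point, 0.975)
  expect_equal(sensitivity(two_by_two(29, 0, 0, 10))$point, 1.0)
  est0 <- sensitivity(two_by_two(0, 0, 5, 5))
  expect_equal(est0$point, 0)
  expect_equal(est0$ci_low, 0)

  expect_equal(specificity(two_by_two(5, 0, 1, 60))$point, 1.0)
  expect_equal(specificity(two_by_two(0, 1, 0, 70))$point, 70 / 71,
               tolerance = 1e-12)
  expect_equal(specificity(two_by_two(1, 3, 1, 0))$point, 0)

  expect_error(sensitivity(two_by_two(0, 3, 0, 7)), "undefined")
  expect_error(specificity(two_by_two(3, 0, 7, 0)), "undefined")
})

test_that("exact CI matches its closed forms at the boundaries", {
  ci <- exact_binomial_ci(0, 10)
  expect_equal(ci[["low"]], 0)
  expect_equal(ci[["high"]], 1 - (0.05 / 2)^(1 / 10), tolerance = 1e-12)
  expect_equal(ci[["high"]], 0.3085, tolerance = 1e-4)

  expect_equal(exact_binomial_ci(10, 10)[["high"]], 1)
  expect_equal(exact_binomial_ci(10, 10)[["low"]], (0.05 / 2)^(1 / 10),
               tolerance = 1e-12)

  mid <- exact_binomial_ci(5, 10)
  expect_true(mid[["low"]] < 0.5 && mid[["high"]] > 0.5)

  expect_error(exact_binomial_ci(5, 4), "k <= n")
  expect_error(exact_binomial_ci(1, 10, alpha = 1.2), "alpha")
})

test_that("exact CI agrees with tail-inversion and binom.test oracles", {
  for (n in c(1L, 7L, 40L)) {
    for (k in 0:n) {
      ours <- exact_binomial_ci(k, n)
      inv <- oracle_exact_ci(k, n)
      expect_equal(ours[["low"]], inv[["low"]], tolerance = 1e-10)
      expect_equal(ours[["high"]], inv[["high"]], tolerance = 1e-10)
      bt <- stats::binom.test(k, n)$conf.int
      expect_equal(unname(ours), c(bt[1], bt[2]), tolerance = 1e-12)
    }
  }
})

test_that("strategy comparison emits one row per strategy and rejects self-reference", {
  ids <- sprintf("a%02d", 1:20)
  ref <- stats::setNames(rep(c(TRUE, FALSE), 10), ids)
  s1 <- ref
  s2 <- stats::setNames(rep(FALSE, 20), ids)
  rows <- compare_strategies(ref, list(text = s1, codes = s2), "derivation")
  expect_identical(nrow(rows), 2L)
  expect_identical(rows$strategy, c("text", "codes"))
  expect_equal(rows$sensitivity, c(1, 0))
  expect_equal(rows$specificity, c(1, 1))
  expect_identical(rows$n, c(20L, 20L))

  expect_error(
    compare_strategies(s1, list(eadhf = s1), "x", reference_label = "eadhf"),
    "itself")

  # bit-identical on re-run
  expect_identical(rows,
                   compare_strategies(ref, list(text = s1, codes = s2),
                                      "derivation"))
})

test_that("comparison rendering reports percentages to one decimal", {
  ref <- stats::setNames(c(rep(TRUE, 40), rep(FALSE, 60)), sprintf("i%02d", 1:100))
  pred <- ref
  pred[c("i01")] <- FALSE   # 39/40 sensitivity
  rows <- compare_strategies(ref, list(eadhf = pred), "derivation-final")
  md <- render_comparison(rows)
  expect_match(md[3], "97.5", fixed = TRUE)
  expect_match(md[3], "100.0", fixed = TRUE)
  csv <- render_comparison(rows, format = "csv")
  expect_match(csv[2], "97.5", fixed = TRUE)
})

test_that("discordance report lists exactly the mismatches, sorted", {
  ids <- c("c3", "a1", "b2", "d4")
  ref <- stats::setNames(c(TRUE, TRUE, FALSE, FALSE), ids)
  pred <- stats::setNames(c(TRUE, FALSE, TRUE, FALSE), ids)
  rep0 <- discordance_report(ref, ref)
  expect_identical(nrow(rep0), 0L)

  rep1 <- discordance_report(pred, ref)
  expect_identical(rep1$admission_id, c("a1", "b2"))
  expect_identical(rep1$predicted, c(FALSE, TRUE))
  expect_identical(rep1$reference_label, c(TRUE, FALSE))
  expect_true(all(rep1$predicted != rep1$reference_label))

  ev <- list(a1 = "verdict-a1", b2 = "verdict-b2", c3 = "x", d4 = "y")
  rep2 <- discordance_report(pred, ref, evidence = ev)
  expect_identical(rep2$evidence, list("verdict-a1", "verdict-b2"))
})
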