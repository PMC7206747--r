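#' Cross-tabulate predictions against a reference standard
#'
#' Builds the 2x2 diagnostic table with the reference standard as column
#' truth: `tp` predicted positive / reference positive, `fp` predicted
#' positive / reference negative, `fn` predicted negative / reference
#' positive, `tn` predicted negative / reference negative.
#'
#' Every admission in `reference` must have a prediction (missing ones are
#' an error listing the ids). Admissions with predictions but no reference
#' label are ignored; their count is recorded in the result and reported
#' via `message()`.
#'
#' @param predictions Named logical vector keyed by admission id (e.g. from
#'   [verdict_predictions()] or [run_code_strategy()]).
#' @param reference Named logical vector keyed by admission id: the
#'   reference-standard labels.
#' @return An object of class `two_by_two` with fields `tp`, `fp`, `fn`,
#'   `tn`, `n`, `n_unlabelled` (predictions ignored for lack of a label).
#' @export
confusion_matrix <- function(predictions, reference) {
  stopifnot(is.logical(predictions), is.logical(reference),
            !is.null(names(predictions)), !is.null(names(reference)))
  if (anyDuplicated(names(reference)) || anyDuplicated(names(predictions))) {
    stop("admission ids must be unique in predictions and reference",
         call. = FALSE)
  }
  missing_pred <- setdiff(names(reference), names(predictions))
  if (length(missing_pred)) {
    stop("no prediction for reference admission(s): ",
         paste(utils::head(missing_pred, 10L), collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(names(predictions), names(reference))
  if (length(extra)) {
    message(length(extra), " prediction(s) without a reference label ignored")
  }
  pred <- predictions[names(reference)]
  two_by_two(
    tp = sum(pred & reference),
    fp = sum(pred & !reference),
    fn = sum(!pred & reference),
    tn = sum(!pred & !reference),
    n_unlabelled = length(extra)
  )
}

#' @rdname confusion_matrix
#' @param tp,fp,fn,tn Non-negative cell counts.
#' @param n_unlabelled Predictions ignored for lack of a reference label.
#' @export
two_by_two <- function(tp, fp, fn, tn, n_unlabelled = 0L) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(cells < 0) || any(cells != trunc(cells))) {
    stop("2x2 cells must be non-negative integers", call. = FALSE)
  }
  structure(
    list(tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn),
         tn = as.integer(tn), n = as.integer(tp + fp + fn + tn),
         n_unlabelled = as.integer(n_unlabelled)),
    class = "two_by_two"
  )
}

#' @export
print.two_by_two <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(predicted = c("positive", "negative"),
                              reference = c("positive", "negative")))
  cat("<two_by_two> n =", x$n, "\n")
  print(m)
  invisible(x)
}

#' Sensitivity and specificity with exact confidence intervals
#'
#' `sensitivity()` is TP / (TP + FN); `specificity()` is TN / (TN + FP).
#' Both carry an exact (Clopper-Pearson) confidence interval at level
#' `1 - alpha` from [exact_binomial_ci()]. A metric whose denominator is
#' zero (no reference positives, resp. negatives) is undefined and raises
#' an error.
#'
#' @param tt A [two_by_two()] table.
#' @param alpha Significance level (default 0.05 for a 95% CI).
#' @return An object of class `accuracy_estimate` with fields `metric`,
#'   `point`, `ci_low`, `ci_high`, `n_numerator`, `n_denominator`, `alpha`.
#' @examples
#' tt <- two_by_two(tp = 39, fp = 0, fn = 1, tn = 60)
#' sensitivity(tt)   # 0.975
#' specificity(tt)   # 1.0
#' @export
sensitivity <- function(tt, alpha = 0.05) {
  stopifnot(inherits(tt, "two_by_two"))
  den <- tt$tp + tt$fn
  if (den == 0L) {
    stop("sensitivity undefined: no reference positives (tp + fn = 0)",
         call. = FALSE)
  }
  accuracy_estimate("sensitivity", tt$tp, den, alpha)
}

#' @rdname sensitivity
#' @export
specificity <- function(tt, alpha = 0.05) {
  stopifnot(inherits(tt, "two_by_two"))
  den <- tt$tn + tt$fp
  if (den == 0L) {
    stop("specificity undefined: no reference negatives (tn + fp = 0)",
         call. = FALSE)
  }
  accuracy_estimate("specificity", tt$tn, den, alpha)
}

accuracy_estimate <- function(metric, k, n, alpha) {
  ci <- exact_binomial_ci(k, n, alpha)
  structure(
    list(metric = metric, point = k / n,
         ci_low = ci[[1L]], ci_high = ci[[2L]],
         n_numerator = as.integer(k), n_denominator = as.integer(n),
         alpha = alpha),
    class = "accuracy_estimate"
  )
}

#' @export
print.accuracy_estimate <- function(x, ...) {
  cat(sprintf("%s: %.1f%% (%d/%d), %.0f%% CI %.1f-%.1f%%\n",
              x$metric, 100 * x$point, x$n_numerator, x$n_denominator,
              100 * (1 - x$alpha), 100 * x$ci_low, 100 * x$ci_high))
  invisible(x)
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' The exact interval for a binomial proportion, computed from beta
#' quantiles: lower bound `qbeta(alpha/2, k, n - k + 1)` (0 when `k = 0`),
#' upper bound `qbeta(1 - alpha/2, k + 1, n - k)` (1 when `k = n`). This is
#' the "exact test for proportions" interval conventionally reported with
#' diagnostic sensitivity and specificity.
#'
#' @param k Number of successes, `0 <= k <= n`.
#' @param n Number of trials, `n >= 1`.
#' @param alpha Significance level in (0, 1); default 0.05.
#' @return Named numeric vector `c(low, high)`.
#' @examples
#' exact_binomial_ci(0, 10)   # upper bound 1 - (alpha/2)^(1/10)
#' exact_binomial_ci(39, 40)
#' @export
exact_binomial_ci <- function(k, n, alpha = 0.05) {
  if (!is.numeric(k) || !is.numeric(n) || length(k) != 1L || length(n) != 1L ||
      n < 1 || k < 0 || k > n || k != trunc(k) || n != trunc(n)) {
    stop("require integer 0 <= k <= n with n >= 1", call. = FALSE)
  }
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must be in (0, 1)", call. = FALSE)
  }
  low <- if (k == 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1)
  high <- if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)
  c(low = low, high = high)
}

#' Compare classification strategies against a reference
#'
#' Builds the comparison table: one row per strategy, each with sensitivity
#' and specificity (point and exact CI) against the given reference. The
#' reference may be the manual/ground-truth standard or another strategy's
#' predictions (set `reference_label` accordingly) — the latter yields the
#' "ICD-9 vs computable phenotype" style of comparison. A strategy may not
#' be compared against itself.
#'
#' @param reference Named logical vector: the reference labels.
#' @param strategies Named list of named logical prediction vectors.
#' @param cohort_label Cohort identifier recorded on each row.
#' @param reference_label Name recorded for the reference (default
#'   `"reference_standard"`); must differ from every strategy name.
#' @param alpha Significance level for the CIs.
#' @return A tibble with columns `cohort_label`, `strategy`, `reference`,
#'   `n`, `sensitivity`, `sens_low`, `sens_high`, `specificity`,
#'   `spec_low`, `spec_high` (proportions in `[0, 1]`).
#' @seealso [render_comparison()] for the percent-formatted report.
#' @export
compare_strategies <- function(reference, strategies, cohort_label,
                               reference_label = "reference_standard",
                               alpha = 0.05) {
  if (!is.list(strategies) || length(strategies) == 0L ||
      is.null(names(strategies)) || any(!nzchar(names(strategies)))) {
    stop("`strategies` must be a non-empty named list", call. = FALSE)
  }
  if (reference_label %in% names(strategies)) {
    stop("a strategy cannot be compared against itself: `",
         reference_label, "`", call. = FALSE)
  }
  rows <- lapply(names(strategies), function(nm) {
    tt <- confusion_matrix(strategies[[nm]], reference)
    se <- sensitivity(tt, alpha)
    sp <- specificity(tt, alpha)
    tibble::tibble(
      cohort_label = cohort_label, strategy = nm, reference = reference_label,
      n = tt$n,
      sensitivity = se$point, sens_low = se$ci_low, sens_high = se$ci_high,
      specificity = sp$point, spec_low = sp$ci_low, spec_high = sp$ci_high
    )
  })
  do.call(rbind, rows)
}

#' Render a strategy-comparison table for reporting
#'
#' Formats the output of [compare_strategies()] with percentages to one
#' decimal place, either as a Markdown table or as CSV text. Positive and
#' negative predictive values are deliberately not part of the report: they
#' depend on the cohort's prevalence and do not transport across settings.
#'
#' @param rows Tibble from [compare_strategies()] (rows from several
#'   cohorts may be concatenated).
#' @param format `"markdown"` or `"csv"`.
#' @return A character vector of lines.
#' @export
render_comparison <- function(rows, format = c("markdown", "csv")) {
  format <- match.arg(format)
  pct <- function(x) sprintf("%.1f", 100 * x)
  if (format == "csv") {
    out <- data.frame(
      cohort = rows$cohort_label, strategy = rows$strategy,
      reference = rows$reference, n = rows$n,
      sensitivity = pct(rows$sensitivity),
      sens_ci = paste0(pct(rows$sens_low), "-", pct(rows$sens_high)),
      specificity = pct(rows$specificity),
      spec_ci = paste0(pct(rows$spec_low), "-", pct(rows$spec_high)),
      stringsAsFactors = FALSE
    )
    con <- textConnection("csv_lines", "w", local = TRUE)
    utils::write.csv(out, con, row.names = FALSE)
    close(con)
    return(csv_lines)
  }
  header <- paste(
    "| Cohort | Strategy | Reference | n | Sensitivity % (95% CI) |",
    "Specificity % (95% CI) |")
  sep <- "|---|---|---|---|---|---|"
  body <- sprintf(
    "| %s | %s | %s | %d | %s (%s-%s) | %s (%s-%s) |",
    rows$cohort_label, rows$strategy, rows$reference, rows$n,
    pct(rows$sensitivity), pct(rows$sens_low), pct(rows$sens_high),
    pct(rows$specificity), pct(rows$spec_low), pct(rows$spec_high)
  )
  c(header, sep, body)
}

#' List admissions where a strategy disagrees with the reference
#'
#' One record per mismatching admission, sorted by admission id, carrying
#' whatever evidence is available (the engine's verdict with kept and
#' suppressed matches, or an admission's code list) so a reviewer can
#' decide whether the dictionary needs another inclusion term (false
#' negatives) or exclusion cue (false positives). This is the report that
#' drives the iterative refinement of the term lists.
#'
#' @param predictions,reference Named logical vectors keyed by admission id.
#' @param evidence Optional evidence store: a `phenotype_result`, or any
#'   named list keyed by admission id.
#' @return A tibble with columns `admission_id`, `predicted`,
#'   `reference_label`, and `evidence` (list-column; `NULL` entries where no
#'   evidence is available).
#' @export
discordance_report <- function(predictions, reference, evidence = NULL) {
  tt_ids <- names(reference)
  missing_pred <- setdiff(tt_ids, names(predictions))
  if (length(missing_pred)) {
    stop("no prediction for reference admission(s): ",
         paste(utils::head(missing_pred, 10L), collapse = ", "), call. = FALSE)
  }
  pred <- predictions[tt_ids]
  mism <- sort(tt_ids[pred != reference])
  ev <- lapply(mism, function(id) {
    if (is.null(evidence)) NULL else evidence[[id]]
  })
  tibble::tibble(
    admission_id = mism,
    predicted = unname(pred[mism]),
    reference_label = unname(reference[mism]),
    evidence = ev
  )
}
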