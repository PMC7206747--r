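#' Run the full phenotyping and evaluation protocol
#'
#' Ties the modules together in the study's workflow: read the note corpus,
#' admission code lists and reference labels; run the computable phenotype
#' and both ICD-9 comparator strategies; evaluate every strategy against
#' the reference standard and the ICD-9 strategies against the phenotype
#' itself; and write the report bundle.
#'
#' Outputs written to `out_dir`:
#' \describe{
#'   \item{`verdicts_eadhf.csv`, `evidence_eadhf.jsonl`}{phenotype verdicts
#'     and evidence trail}
#'   \item{`verdicts_icd9_acute.csv`, `verdicts_icd9_all.csv`}{comparator
#'     verdicts}
#'   \item{`comparison_vs_reference.csv`}{all three strategies vs the
#'     reference standard}
#'   \item{`comparison_vs_eadhf.csv`}{ICD-9 strategies vs the phenotype as
#'     reference}
#'   \item{`report.md`}{both tables rendered as Markdown}
#'   \item{`discordance.jsonl`}{phenotype-vs-reference mismatches with
#'     evidence}
#'   \item{`provenance.json`}{input-file hashes, dictionary hash, alpha and
#'     cohort label, sufficient to reproduce the run bit-for-bit}
#' }
#'
#' Any stage failure is re-raised with the stage name and partial outputs
#' are removed.
#'
#' @param notes_path JSON Lines note corpus ([read_note_corpus()]).
#' @param codes_path Long-format admission/ICD-9 CSV ([read_icd9_codes()]).
#' @param reference_path Reference-label CSV ([read_reference_labels()]).
#' @param out_dir Output directory (created if needed).
#' @param dictionary A [term_dictionary()], or a path readable by
#'   [read_term_dictionary()]; default [default_dictionary()].
#' @param alpha Significance level for the exact CIs.
#' @param cohort_label Label recorded on report rows.
#' @return Invisibly, a list with the comparison tibbles (`vs_reference`,
#'   `vs_eadhf`), the `discordance` tibble and the output paths.
#' @export
run_full_protocol <- function(notes_path, codes_path, reference_path,
                              out_dir, dictionary = default_dictionary(),
                              alpha = 0.05, cohort_label = "cohort") {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(out_dir, recursive = TRUE)
      stop("stage `", name, "` failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  if (is.character(dictionary)) {
    dictionary <- stage("load_dictionary", read_term_dictionary(dictionary))
  }
  stopifnot(inherits(dictionary, "term_dictionary"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  notes <- stage("read_notes", read_note_corpus(notes_path))
  admissions <- stage("read_codes", read_icd9_codes(codes_path))
  labels <- stage("read_reference", read_reference_labels(reference_path))
  reference <- stats::setNames(labels$adhf, labels$admission_id)

  result <- stage("phenotype", run_phenotype(notes, dictionary))
  eadhf <- verdict_predictions(result)
  icd9_acute <- stage("icd9_acute",
                      run_code_strategy(admissions, acute_hf_codes()))
  icd9_all <- stage("icd9_all",
                    run_code_strategy(admissions, all_hf_codes()))

  # code lists may omit code-free admissions; they are code-negative
  icd9_acute <- fill_missing(icd9_acute, names(reference))
  icd9_all <- fill_missing(icd9_all, names(reference))

  vs_reference <- stage("evaluate", compare_strategies(
    reference,
    list(eadhf = eadhf, icd9_acute_hf = icd9_acute, icd9_all_hf = icd9_all),
    cohort_label = cohort_label, alpha = alpha))
  vs_eadhf <- stage("evaluate_vs_eadhf", compare_strategies(
    eadhf,
    list(icd9_acute_hf = icd9_acute, icd9_all_hf = icd9_all),
    cohort_label = cohort_label, reference_label = "eadhf", alpha = alpha))
  disc <- stage("discordance",
                discordance_report(eadhf, reference, evidence = result))

  paths <- list(
    verdicts = file.path(out_dir, "verdicts_eadhf.csv"),
    evidence = file.path(out_dir, "evidence_eadhf.jsonl"),
    icd9_acute = file.path(out_dir, "verdicts_icd9_acute.csv"),
    icd9_all = file.path(out_dir, "verdicts_icd9_all.csv"),
    vs_reference = file.path(out_dir, "comparison_vs_reference.csv"),
    vs_eadhf = file.path(out_dir, "comparison_vs_eadhf.csv"),
    report = file.path(out_dir, "report.md"),
    discordance = file.path(out_dir, "discordance.jsonl"),
    provenance = file.path(out_dir, "provenance.json")
  )
  stage("write_outputs", {
    write_verdicts(result, paths$verdicts, paths$evidence)
    write_prediction_csv(icd9_acute, paths$icd9_acute)
    write_prediction_csv(icd9_all, paths$icd9_all)
    utils::write.csv(vs_reference, paths$vs_reference, row.names = FALSE)
    utils::write.csv(vs_eadhf, paths$vs_eadhf, row.names = FALSE)
    writeLines(c(
      paste0("# Strategy performance — ", cohort_label),
      "", "## Strategies vs reference standard", "",
      render_comparison(vs_reference),
      "", "## ICD-9 strategies vs computable phenotype", "",
      render_comparison(vs_eadhf)
    ), paths$report)
    write_discordance(disc, paths$discordance)
    write_provenance(paths$provenance, notes_path, codes_path,
                     reference_path, dictionary, alpha, cohort_label)
  })
  invisible(list(vs_reference = vs_reference, vs_eadhf = vs_eadhf,
                 discordance = disc, paths = paths))
}

fill_missing <- function(pred, ids) {
  out <- stats::setNames(rep(FALSE, length(ids)), ids)
  common <- intersect(ids, names(pred))
  out[common] <- pred[common]
  # keep predictions for admissions outside the reference too
  extra <- setdiff(names(pred), ids)
  c(out, pred[extra])
}

write_prediction_csv <- function(pred, path) {
  utils::write.csv(
    data.frame(admission_id = names(pred), adhf = as.integer(pred)),
    path, row.names = FALSE)
  invisible(path)
}

write_discordance <- function(disc, path) {
  lines <- vapply(seq_len(nrow(disc)), function(i) {
    ev <- disc$evidence[[i]]
    rec <- list(admission_id = disc$admission_id[i],
                predicted = disc$predicted[i],
                reference_label = disc$reference_label[i])
    if (inherits(ev, "phenotype_verdict")) {
      rec$evidence <- list(kept_matches = ev$kept_matches,
                           suppressed_matches = ev$suppressed_matches)
    } else if (!is.null(ev)) {
      rec$evidence <- ev
    }
    as.character(jsonlite::toJSON(rec, auto_unbox = TRUE, dataframe = "rows",
                                  na = "null", digits = NA))
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

write_provenance <- function(path, notes_path, codes_path, reference_path,
                             dictionary, alpha, cohort_label) {
  dict_file <- tempfile(fileext = ".json")
  on.exit(unlink(dict_file))
  write_term_dictionary(dictionary, dict_file)
  prov <- list(
    inputs = list(
      notes = list(path = notes_path,
                   md5 = unname(tools::md5sum(notes_path))),
      codes = list(path = codes_path,
                   md5 = unname(tools::md5sum(codes_path))),
      reference = list(path = reference_path,
                       md5 = unname(tools::md5sum(reference_path)))
    ),
    dictionary_md5 = unname(tools::md5sum(dict_file)),
    alpha = alpha,
    cohort_label = cohort_label,
    package_version = as.character(utils::packageVersion("adhfphenotype"))
  )
  jsonlite::write_json(prov, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
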