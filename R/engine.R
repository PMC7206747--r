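#' Classify one hospital admission for ADHF
#'
#' Runs the computable phenotype over all notes of a single admission: for
#' each note, each section whose canonical name is in the dictionary's
#' `scoped_sections` is normalized, scanned for inclusion phrases, and
#' filtered through the exclusion rule. The admission is called positive iff
#' at least one match survives exclusion filtering anywhere in its notes.
#' The verdict carries the full evidence trail — kept and suppressed matches
#' with note id, section, offsets and suppressing cue — so discordances can
#' be reviewed.
#'
#' The pipeline is deterministic: the same notes and dictionary always give
#' the same verdict, and the verdict does not depend on note order (evidence
#' is sorted by note id, section position and offset).
#'
#' @param notes List of [clinical_note] objects sharing one admission id (an
#'   empty list yields a negative verdict).
#' @param dictionary A [term_dictionary()].
#' @param admission_id Admission id, required only when `notes` is empty.
#' @return An object of class `phenotype_verdict`: a list with
#'   `admission_id`, `adhf` (logical), `kept_matches`, `suppressed_matches`
#'   (tibbles with a `note_id` column in addition to the match columns).
#' @export
classify_admission <- function(notes, dictionary, admission_id = NULL) {
  stopifnot(inherits(dictionary, "term_dictionary"))
  if (length(notes) == 0L) {
    if (is.null(admission_id)) {
      stop("`admission_id` is required when `notes` is empty", call. = FALSE)
    }
    return(new_verdict(admission_id, empty_evidence(), empty_evidence()))
  }
  ids <- unique(vapply(notes, function(x) x$admission_id, character(1)))
  if (length(ids) != 1L) {
    stop("notes span multiple admissions: ", paste(ids, collapse = ", "),
         call. = FALSE)
  }
  evidence <- list()
  for (note in notes) {
    sec <- note$sections
    sec <- sec[sec$name %in% dictionary$scoped_sections, , drop = FALSE]
    for (j in seq_len(nrow(sec))) {
      body <- substring(note$text, sec$start[j] + 1L, sec$end[j])
      m <- find_inclusion_matches(body, dictionary, sec$name[j])
      if (nrow(m) == 0L) next
      m <- apply_exclusions(m, body, dictionary)
      m$note_id <- note$note_id
      m$section_start <- sec$start[j]
      evidence[[length(evidence) + 1L]] <- m
    }
  }
  if (length(evidence)) {
    ev <- do.call(rbind, evidence)
    ev <- ev[order(ev$note_id, ev$section_start, ev$start), , drop = FALSE]
    ev <- ev[, c("note_id", "term", "section_name", "start", "end",
                 "sentence_index", "suppressed_by")]
  } else {
    ev <- empty_evidence()
  }
  kept <- ev[is.na(ev$suppressed_by), , drop = FALSE]
  suppressed <- ev[!is.na(ev$suppressed_by), , drop = FALSE]
  new_verdict(ids, kept, suppressed)
}

empty_evidence <- function() {
  tibble::new_tibble(list(
    note_id = character(0), term = character(0), section_name = character(0),
    start = integer(0), end = integer(0), sentence_index = integer(0),
    suppressed_by = character(0)
  ), nrow = 0L)
}

new_verdict <- function(admission_id, kept, suppressed) {
  structure(
    list(admission_id = as.character(admission_id),
         adhf = nrow(kept) > 0L,
         kept_matches = tibble::as_tibble(kept),
         suppressed_matches = tibble::as_tibble(suppressed)),
    class = "phenotype_verdict"
  )
}

#' @export
print.phenotype_verdict <- function(x, ...) {
  cat("<phenotype_verdict> admission ", x$admission_id, ": ",
      if (x$adhf) "ADHF positive" else "ADHF negative",
      " (", nrow(x$kept_matches), " kept, ",
      nrow(x$suppressed_matches), " suppressed match",
      if (nrow(x$suppressed_matches) == 1L) "" else "es", ")\n", sep = "")
  invisible(x)
}

#' Run the phenotype over a whole note corpus
#'
#' Groups notes by admission id and applies [classify_admission()] to each
#' admission. Every admission present in the corpus receives exactly one
#' verdict; admissions are processed in sorted id order so the result is
#' independent of note order in the corpus.
#'
#' @param notes List of [clinical_note] objects (the corpus).
#' @param dictionary A [term_dictionary()].
#' @return A named list of `phenotype_verdict` objects keyed by admission
#'   id, of class `phenotype_result`.
#' @seealso [verdict_table()] to flatten verdicts to a tibble,
#'   [verdict_predictions()] for the logical vector evaluation expects.
#' @export
run_phenotype <- function(notes, dictionary) {
  if (length(notes) == 0L) {
    return(structure(stats::setNames(list(), character(0)),
                     class = "phenotype_result"))
  }
  adm <- vapply(notes, function(x) x$admission_id, character(1))
  ids <- sort(unique(adm))
  verdicts <- lapply(ids, function(id) {
    classify_admission(notes[adm == id], dictionary)
  })
  structure(stats::setNames(verdicts, ids), class = "phenotype_result")
}

#' @export
print.phenotype_result <- function(x, ...) {
  pos <- sum(vapply(x, function(v) v$adhf, logical(1)))
  cat("<phenotype_result> ", length(x), " admissions, ",
      pos, " ADHF positive\n", sep = "")
  invisible(x)
}

#' Flatten phenotype verdicts to a table
#'
#' @param result A `phenotype_result` from [run_phenotype()], or a list of
#'   `phenotype_verdict` objects.
#' @return A tibble with columns `admission_id`, `adhf`, `n_kept`,
#'   `n_suppressed`.
#' @export
verdict_table <- function(result) {
  tibble::tibble(
    admission_id = unname(vapply(result, function(v) v$admission_id,
                                 character(1))),
    adhf = unname(vapply(result, function(v) v$adhf, logical(1))),
    n_kept = unname(vapply(result, function(v) nrow(v$kept_matches),
                           integer(1))),
    n_suppressed = unname(vapply(result, function(v) nrow(v$suppressed_matches),
                                 integer(1)))
  )
}

#' @rdname verdict_table
#' @return `verdict_predictions()` returns a named logical vector keyed by
#'   admission id, the prediction format the evaluation layer consumes.
#' @export
verdict_predictions <- function(result) {
  stats::setNames(vapply(result, function(v) v$adhf, logical(1)),
                  vapply(result, function(v) v$admission_id, character(1)))
}

#' Write phenotype verdicts and evidence to disk
#'
#' Verdicts go to CSV (`admission_id`, `adhf` as 0/1, `n_kept`,
#' `n_suppressed`); the optional evidence file is JSON Lines with one
#' verdict per line including the kept and suppressed match tables.
#'
#' @param result A `phenotype_result`.
#' @param path Output CSV path.
#' @param evidence_path Optional JSON Lines path for the evidence trail.
#' @return `path`, invisibly.
#' @export
write_verdicts <- function(result, path, evidence_path = NULL) {
  tab <- verdict_table(result)
  tab$adhf <- as.integer(tab$adhf)
  utils::write.csv(tab, path, row.names = FALSE)
  if (!is.null(evidence_path)) {
    lines <- vapply(result, function(v) {
      jsonlite::toJSON(
        list(admission_id = v$admission_id, adhf = v$adhf,
             kept_matches = v$kept_matches,
             suppressed_matches = v$suppressed_matches),
        auto_unbox = TRUE, dataframe = "rows", na = "null", digits = NA)
    }, character(1))
    writeLines(lines, evidence_path, useBytes = TRUE)
  }
  invisible(path)
}

#' Read phenotype or comparator predictions from a verdict CSV
#'
#' @param path CSV with columns `admission_id` and `adhf` (0/1).
#' @return Named logical vector keyed by admission id.
#' @export
read_predictions <- function(path) {
  if (!file.exists(path)) stop("prediction file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character")
  if (!all(c("admission_id", "adhf") %in% names(df))) {
    stop("prediction CSV must have columns admission_id, adhf", call. = FALSE)
  }
  stats::setNames(df$adhf %in% c("1", "TRUE", "true"), df$admission_id)
}
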