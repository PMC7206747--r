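#' Read a clinical-note corpus from JSON Lines
#'
#' One note per line, as a JSON object with fields `note_id`,
#' `admission_id`, `timestamp` (ISO-8601), `text`, and optionally
#' `patient_id` and pre-segmented `sections` (array of objects with `name`,
#' `start`, `end`; 0-based half-open offsets). When `sections` is absent the
#' note is segmented from its raw text with [segment_note()]. Input order is
#' preserved.
#'
#' @param path Path to a `.jsonl` file.
#' @param section_patterns Header patterns used when a record carries raw
#'   text only; see [default_section_patterns()].
#' @return A list of [clinical_note] objects, in file order.
#' @export
read_note_corpus <- function(path, section_patterns = default_section_patterns()) {
  if (!file.exists(path)) stop("note corpus not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  notes <- vector("list", length(lines))
  seen <- character(0)
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE),
                    error = function(e) {
                      stop("line ", i, ": malformed JSON record (",
                           conditionMessage(e), ")", call. = FALSE)
                    })
    for (field in c("note_id", "admission_id", "timestamp", "text")) {
      if (is.null(rec[[field]]) || is.na(rec[[field]])) {
        stop("line ", i, ": record missing field `", field, "`", call. = FALSE)
      }
    }
    if (rec$note_id %in% seen) {
      stop("line ", i, ": duplicate note_id `", rec$note_id, "`", call. = FALSE)
    }
    seen <- c(seen, rec$note_id)
    sections <- NULL
    if (!is.null(rec$sections) && length(rec$sections)) {
      sections <- as.data.frame(rec$sections)
    }
    notes[[i]] <- clinical_note(
      note_id = rec$note_id, admission_id = rec$admission_id,
      timestamp = rec$timestamp, text = rec$text, sections = sections,
      patient_id = rec$patient_id %||% NA_character_,
      section_patterns = section_patterns
    )
  }
  notes
}

#' Write a clinical-note corpus to JSON Lines
#'
#' Inverse of [read_note_corpus()]: note ids, admission ids, timestamps,
#' texts and section tables round-trip exactly.
#'
#' @param notes List of [clinical_note] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_note_corpus <- function(notes, path) {
  lines <- vapply(notes, function(note) {
    stopifnot(inherits(note, "clinical_note"))
    rec <- list(
      note_id = note$note_id,
      admission_id = note$admission_id,
      timestamp = format(note$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
      text = note$text,
      sections = note$sections
    )
    if (!is.na(note$patient_id)) rec$patient_id <- note$patient_id
    jsonlite::toJSON(rec, auto_unbox = TRUE, dataframe = "rows", digits = NA)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read per-admission ICD-9 code lists
#'
#' Long-format CSV with columns `admission_id`, `icd9_code`; returns one row
#' per admission with the codes gathered into a list-column.
#'
#' @param path Path to the CSV.
#' @return A tibble with columns `admission_id` (character) and `icd9_codes`
#'   (list of character vectors).
#' @export
read_icd9_codes <- function(path) {
  if (!file.exists(path)) stop("code file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character")
  req <- c("admission_id", "icd9_code")
  if (!all(req %in% names(df))) {
    stop("code CSV must have columns admission_id, icd9_code", call. = FALSE)
  }
  ids <- unique(df$admission_id)
  codes <- lapply(ids, function(id) df$icd9_code[df$admission_id == id])
  tibble::tibble(admission_id = ids, icd9_codes = codes)
}

#' @rdname read_icd9_codes
#' @param admissions A tibble/data frame with `admission_id` and list-column
#'   `icd9_codes` (as returned by [read_icd9_codes()] or [generate_cohort()]).
#' @export
write_icd9_codes <- function(admissions, path) {
  long <- data.frame(
    admission_id = rep(admissions$admission_id,
                       lengths(admissions$icd9_codes)),
    icd9_code = unlist(admissions$icd9_codes, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Read / write admission-level reference labels
#'
#' CSV with columns `admission_id`, `adhf` (0/1), `source`
#' (`manual_review` or `synthetic_truth`). The source column keeps synthetic
#' ground truth from being conflated with expert chart review.
#'
#' @param path Path to the CSV.
#' @return A tibble with columns `admission_id`, `adhf` (logical), `source`.
#' @export
read_reference_labels <- function(path) {
  if (!file.exists(path)) stop("label file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character")
  req <- c("admission_id", "adhf")
  if (!all(req %in% names(df))) {
    stop("label CSV must have columns admission_id, adhf", call. = FALSE)
  }
  if (anyDuplicated(df$admission_id)) {
    stop("duplicate admission_id in label file: ",
         paste(unique(df$admission_id[duplicated(df$admission_id)]),
               collapse = ", "), call. = FALSE)
  }
  src <- if ("source" %in% names(df)) df$source else "manual_review"
  bad <- !src %in% c("manual_review", "synthetic_truth")
  if (any(bad)) stop("unknown label source: ", unique(src[bad]), call. = FALSE)
  tibble::tibble(
    admission_id = df$admission_id,
    adhf = df$adhf %in% c("1", "TRUE", "true"),
    source = src
  )
}

#' @rdname read_reference_labels
#' @param labels A tibble as returned by [read_reference_labels()].
#' @export
write_reference_labels <- function(labels, path) {
  utils::write.csv(
    data.frame(admission_id = labels$admission_id,
               adhf = as.integer(labels$adhf),
               source = labels$source),
    path, row.names = FALSE
  )
  invisible(path)
}
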