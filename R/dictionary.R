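#' Build a phenotype term dictionary
#'
#' The term dictionary is the computable phenotype's definition: the
#' inclusion phrases whose presence in a scoped note section counts as
#' evidence of acute decompensated heart failure (ADHF), the exclusion cues
#' whose proximity suppresses a hit, the set of section names the search is
#' restricted to, and the matching options.
#'
#' @param inclusion_terms Character vector of inclusion phrases (non-empty).
#' @param exclusion_terms Character vector of exclusion cues (may be empty).
#' @param scoped_sections Character vector of canonical section names the
#'   search is restricted to.
#' @param case_insensitive Match case-insensitively? Default `TRUE`.
#' @param word_boundary Require phrase occurrences to align with token
#'   boundaries, so an abbreviation such as `"adhf"` never matches inside a
#'   longer token. Default `TRUE`.
#' @param exclusion_scope `"sentence"` (an exclusion cue anywhere in the
#'   sentence containing a match suppresses it) or `"window"` (a cue within
#'   `window_tokens` tokens before the match suppresses it).
#' @param window_tokens Window width in tokens for `exclusion_scope =
#'   "window"`; must be >= 1.
#'
#' @return An object of class `term_dictionary`.
#' @seealso [default_dictionary()] for the packaged ADHF definition,
#'   [read_term_dictionary()] to load one from YAML/JSON.
#' @examples
#' d <- term_dictionary(
#'   inclusion_terms = c("acute decompensated heart failure", "adhf"),
#'   exclusion_terms = c("prior", "rule out", "negative for"),
#'   scoped_sections = c("principal_diagnosis", "brief_hospital_course")
#' )
#' d
#' @export
term_dictionary <- function(inclusion_terms,
                            exclusion_terms = character(0),
                            scoped_sections = default_scoped_sections(),
                            case_insensitive = TRUE,
                            word_boundary = TRUE,
                            exclusion_scope = c("sentence", "window"),
                            window_tokens = 5L) {
  exclusion_scope <- match.arg(exclusion_scope)
  inclusion_terms <- unique(as.character(inclusion_terms))
  exclusion_terms <- unique(as.character(exclusion_terms))
  scoped_sections <- unique(as.character(scoped_sections))
  if (length(inclusion_terms) == 0L || any(!nzchar(trimws(inclusion_terms)))) {
    stop("`inclusion_terms` must be a non-empty set of non-blank phrases",
         call. = FALSE)
  }
  overlap <- intersect(tolower(inclusion_terms), tolower(exclusion_terms))
  if (length(overlap)) {
    stop("phrase(s) present in both inclusion and exclusion lists: ",
         paste(overlap, collapse = ", "), call. = FALSE)
  }
  if (exclusion_scope == "window" &&
      (!is.numeric(window_tokens) || window_tokens < 1)) {
    stop("`window_tokens` must be >= 1 under window scoping", call. = FALSE)
  }
  norm <- function(x) {
    vapply(x, function(p) as.character(normalize_text(p, case_insensitive)),
           character(1), USE.NAMES = FALSE)
  }
  structure(
    list(
      inclusion_terms = inclusion_terms,
      exclusion_terms = exclusion_terms,
      scoped_sections = scoped_sections,
      match_options = list(
        case_insensitive = isTRUE(case_insensitive),
        word_boundary = isTRUE(word_boundary),
        exclusion_scope = exclusion_scope,
        window_tokens = as.integer(window_tokens)
      ),
      # phrases pre-normalized at construction so matching need not redo it
      norm_inclusion = norm(inclusion_terms),
      norm_exclusion = norm(exclusion_terms)
    ),
    class = "term_dictionary"
  )
}

#' @export
print.term_dictionary <- function(x, ...) {
  cat("<term_dictionary>\n")
  cat("  inclusion terms:", length(x$inclusion_terms), "\n")
  cat("  exclusion terms:", length(x$exclusion_terms), "\n")
  cat("  scoped sections:", paste(x$scoped_sections, collapse = ", "), "\n")
  cat("  matching: ",
      if (x$match_options$case_insensitive) "case-insensitive" else "case-sensitive",
      ", ", if (x$match_options$word_boundary) "word-boundary" else "substring",
      ", ", x$match_options$exclusion_scope, "-scoped exclusions",
      if (x$match_options$exclusion_scope == "window")
        paste0(" (", x$match_options$window_tokens, " tokens)") else "",
      "\n", sep = "")
  invisible(x)
}

#' Canonical section names the ADHF search is scoped to
#'
#' Principal diagnosis, secondary diagnoses, chief complaint / reason for
#' visit, and brief hospital course: the note sections a hospital discharge
#' summary states its diagnoses in, and the ones the free-text search reads.
#'
#' @return A character vector of canonical snake_case section names.
#' @export
default_scoped_sections <- function() {
  c("principal_diagnosis", "secondary_diagnoses",
    "chief_complaint", "brief_hospital_course")
}

#' The packaged ADHF term dictionary
#'
#' Default inclusion list covering the standard surface forms, synonyms and
#' acronyms under which acute decompensated heart failure is documented in
#' hospital notes, plus the default exclusion cues. The three core cues —
#' `"prior"`, `"rule out"`, `"negative for"` — flag historical, speculative
#' and negated mentions; the remaining cues are common paraphrases of the
#' same three ideas. Any production use should review and, if needed,
#' override this list via [term_dictionary()] or [read_term_dictionary()]:
#' term lists are institution-specific.
#'
#' @inheritParams term_dictionary
#' @return An object of class `term_dictionary`.
#' @examples
#' default_dictionary()
#' @export
default_dictionary <- function(exclusion_scope = "sentence",
                               window_tokens = 5L) {
  term_dictionary(
    inclusion_terms = c(
      "acute decompensated heart failure",
      "acute on chronic heart failure",
      "decompensated heart failure",
      "decompensated chf",
      "acute chf",
      "acute heart failure",
      "heart failure exacerbation",
      "chf exacerbation",
      "acute systolic heart failure",
      "acute diastolic heart failure",
      "acute on chronic systolic heart failure",
      "acute on chronic diastolic heart failure",
      "adhf"
    ),
    exclusion_terms = c(
      "prior", "rule out", "negative for",
      "history of", "no evidence of", "resolved", "ruled out", "r/o"
    ),
    scoped_sections = default_scoped_sections(),
    exclusion_scope = exclusion_scope,
    window_tokens = window_tokens
  )
}

#' Read / write a term dictionary as YAML or JSON
#'
#' The on-disk form has keys `inclusion_terms`, `exclusion_terms`,
#' `scoped_sections` and `match_options` (with `case_insensitive`,
#' `word_boundary`, `exclusion_scope`, `window_tokens`). Format is chosen by
#' file extension (`.yaml`/`.yml` vs `.json`).
#'
#' @param path File path.
#' @return `read_term_dictionary()` returns a `term_dictionary`;
#'   `write_term_dictionary()` returns `path` invisibly.
#' @export
read_term_dictionary <- function(path) {
  if (!file.exists(path)) stop("dictionary file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  opts <- raw$match_options %||% list()
  term_dictionary(
    inclusion_terms = unlist(raw$inclusion_terms),
    exclusion_terms = as.character(unlist(raw$exclusion_terms)),
    scoped_sections = unlist(raw$scoped_sections) %||% default_scoped_sections(),
    case_insensitive = opts$case_insensitive %||% TRUE,
    word_boundary = opts$word_boundary %||% TRUE,
    exclusion_scope = opts$exclusion_scope %||% "sentence",
    window_tokens = opts$window_tokens %||% 5L
  )
}

#' @rdname read_term_dictionary
#' @param dictionary A `term_dictionary`.
#' @export
write_term_dictionary <- function(dictionary, path) {
  stopifnot(inherits(dictionary, "term_dictionary"))
  x <- unclass(dictionary)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
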