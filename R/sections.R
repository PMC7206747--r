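#' Default note section header patterns
#'
#' A named character vector mapping canonical snake_case section names to
#' case-insensitive regular expressions matched at line starts. The defaults
#' cover the discharge-summary headers used by the ADHF search (principal
#' diagnosis, secondary diagnoses, chief complaint / reason for visit, brief
#' hospital course) plus common distractor sections; other EHRs label their
#' sections differently, so the mapping is a plain vector users can replace.
#'
#' @return Named character vector: `names()` are canonical section names,
#'   values are regexes for the header text (the header plus an optional
#'   colon/dash is excluded from the section body).
#' @export
default_section_patterns <- function() {
  c(
    principal_diagnosis = "principal diagnosis",
    secondary_diagnoses = "secondary diagnos[ei]s",
    chief_complaint = "chief complaint(?:\\s*/\\s*reason for visit)?|reason for visit",
    brief_hospital_course = "brief hospital course|hospital course",
    past_medical_history = "past medical history",
    family_history = "family history",
    medications = "medications|discharge medications",
    other = "impression|assessment|plan"
  )
}

#' Split raw note text into named sections
#'
#' Scans the note line-by-line for section headers. Each matched header opens
#' a section that extends to the next matched header (or end of text); the
#' header itself, plus an optional trailing `:` or `-` and whitespace, is not
#' part of the section body. Headers are matched case-insensitively and must
#' start at the beginning of a line. Text before the first header becomes a
#' section named `"preamble"`; text with no recognized header is a single
#' preamble section.
#'
#' Offsets are 0-based half-open positions into `raw_text` (the interchange
#' convention used throughout the package); use [section_text()] to extract
#' the body of a section without manual indexing.
#'
#' @param raw_text The full note text.
#' @param section_patterns Named character vector of header regexes as in
#'   [default_section_patterns()]; earlier entries win when two patterns
#'   match at the same position.
#' @return A data frame with columns `name`, `start`, `end` (0-based
#'   half-open, body only), ordered by `start`. Empty text yields zero rows.
#' @examples
#' segment_note("Principal Diagnosis: ADHF\nBrief Hospital Course: improved")
#' @export
segment_note <- function(raw_text, section_patterns = default_section_patterns()) {
  stopifnot(is.character(raw_text), length(raw_text) == 1L, !is.na(raw_text))
  if (length(section_patterns) == 0L || is.null(names(section_patterns))) {
    stop("`section_patterns` must be a non-empty named vector", call. = FALSE)
  }
  if (!nzchar(raw_text)) {
    return(section_df(character(0), integer(0), integer(0)))
  }

  n <- nchar(raw_text)
  # candidate headers: for each pattern, anchored at line starts
  hits <- list()
  for (i in seq_along(section_patterns)) {
    pat <- paste0("(?im)^[ \\t]*(?:", section_patterns[[i]],
                  ")[ \\t]*[:\\-]?[ \\t]*")
    m <- gregexpr(pat, raw_text, perl = TRUE)[[1]]
    if (m[1L] != -1L) {
      starts <- as.integer(m)
      hits[[length(hits) + 1L]] <- list(
        name = rep(names(section_patterns)[i], length(starts)),
        start = starts,                              # header start, 1-based
        body = starts + attr(m, "match.length"),     # body start, 1-based
        rank = rep(i, length(starts))
      )
    }
  }
  if (length(hits) == 0L) {
    return(section_df("preamble", 0L, n))
  }
  h_name <- unlist(lapply(hits, `[[`, "name"), use.names = FALSE)
  h_start <- unlist(lapply(hits, `[[`, "start"), use.names = FALSE)
  h_body <- unlist(lapply(hits, `[[`, "body"), use.names = FALSE)
  h_rank <- unlist(lapply(hits, `[[`, "rank"), use.names = FALSE)
  o <- order(h_start, h_rank)
  h_name <- h_name[o]; h_start <- h_start[o]; h_body <- h_body[o]
  # at each position, the first pattern in the vector wins
  dup <- duplicated(h_start)
  h_name <- h_name[!dup]; h_start <- h_start[!dup]; h_body <- h_body[!dup]
  # drop headers nested inside an earlier header's match span
  keep <- rep(TRUE, length(h_start))
  for (i in seq_along(h_start)[-1L]) {
    if (h_start[i] < h_body[i - 1L] && keep[i - 1L]) keep[i] <- FALSE
  }
  h_name <- h_name[keep]; h_start <- h_start[keep]; h_body <- h_body[keep]

  starts <- h_body - 1L                      # 0-based body start
  ends <- c(h_start[-1L] - 1L, n)            # 0-based half-open end
  out <- section_df(h_name, starts, pmax(starts, ends))
  if (h_start[1L] > 1L) {
    pre <- substr(raw_text, 1L, h_start[1L] - 1L)
    if (nzchar(trimws(pre))) {
      out <- rbind(section_df("preamble", 0L, h_start[1L] - 1L), out)
      rownames(out) <- NULL
    }
  }
  out
}

# minimal-allocation data.frame constructor for section tables
section_df <- function(name, start, end) {
  structure(list(name = as.character(name), start = as.integer(start),
                 end = as.integer(end)),
            class = "data.frame", row.names = c(NA, -length(name)))
}

#' Construct a clinical note
#'
#' A `clinical_note` is a timestamped free-text note tied to one hospital
#' admission, carrying its raw text and a table of named sections with
#' character offsets. If `sections` is omitted the note is segmented with
#' [segment_note()].
#'
#' @param note_id,admission_id Opaque identifier strings.
#' @param timestamp A `POSIXct`, or an ISO-8601 string parsed as UTC.
#' @param text Full note text.
#' @param sections Optional section table (`name`, `start`, `end`; 0-based
#'   half-open offsets into `text`).
#' @param patient_id Optional patient identifier.
#' @param section_patterns Passed to [segment_note()] when `sections` is `NULL`.
#' @return An object of class `clinical_note`.
#' @export
clinical_note <- function(note_id, admission_id, timestamp, text,
                          sections = NULL, patient_id = NA_character_,
                          section_patterns = default_section_patterns()) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.character(timestamp)) {
    ts <- as.POSIXct(timestamp, tz = "UTC",
                     tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                                    "%Y-%m-%d"))
  } else {
    ts <- as.POSIXct(timestamp, tz = "UTC")
  }
  if (is.na(ts)) stop("unparseable timestamp for note ", note_id, call. = FALSE)
  if (is.null(sections)) {
    sections <- segment_note(text, section_patterns)
  } else {
    sections <- as.data.frame(sections)[, c("name", "start", "end")]
    sections$start <- as.integer(sections$start)
    sections$end <- as.integer(sections$end)
  }
  note <- structure(
    list(note_id = as.character(note_id),
         admission_id = as.character(admission_id),
         patient_id = as.character(patient_id),
         timestamp = ts, text = text, sections = sections),
    class = "clinical_note"
  )
  validate_clinical_note(note)
  note
}

validate_clinical_note <- function(note) {
  s <- note$sections
  n <- nchar(note$text)
  if (nrow(s)) {
    if (any(s$start < 0L) || any(s$end > n) || any(s$start > s$end)) {
      stop("note ", note$note_id,
           ": section offsets out of bounds of the note text", call. = FALSE)
    }
    if (is.unsorted(s$start)) {
      stop("note ", note$note_id, ": sections must be ordered by start offset",
           call. = FALSE)
    }
    if (nrow(s) > 1L && any(s$start[-1L] < s$end[-nrow(s)])) {
      stop("note ", note$note_id, ": sections overlap", call. = FALSE)
    }
  }
  invisible(note)
}

#' Extract the body text of note sections
#'
#' @param note A `clinical_note`.
#' @param name Optional canonical section name; when given, returns the
#'   bodies of the matching sections only.
#' @return Character vector of section bodies, named by section name.
#' @export
section_text <- function(note, name = NULL) {
  stopifnot(inherits(note, "clinical_note"))
  s <- note$sections
  if (!is.null(name)) s <- s[s$name %in% name, , drop = FALSE]
  out <- substring(note$text, s$start + 1L, s$end)
  names(out) <- s$name
  out
}

#' @export
print.clinical_note <- function(x, ...) {
  cat("<clinical_note ", x$note_id, "> admission ", x$admission_id,
      ", ", format(x$timestamp, "%Y-%m-%d %H:%M", tz = "UTC"),
      " UTC, ", nchar(x$text), " chars, sections: ",
      paste(x$sections$name, collapse = ", "), "\n", sep = "")
  invisible(x)
}
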