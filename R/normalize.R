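#' Normalize clinical text for phrase matching
#'
#' Canonicalizes a piece of note text so that dictionary phrases match
#' regardless of case, whitespace layout, and typographic character variants:
#' curly quotes become straight quotes, Unicode hyphen/dash variants become
#' `-`, runs of whitespace (including line breaks) collapse to a single space,
#' and, when `case_insensitive`, the result is lowercased. Leading and
#' trailing whitespace is dropped.
#'
#' The transformation is offset-preserving: the returned string carries an
#' `offset_map` attribute giving, for every character of the normalized text,
#' the 1-based index of the character it came from in `text`, so match
#' positions found in normalized space can be mapped back onto the original
#' note. A `hard_breaks` attribute records the normalized positions of spaces
#' that absorbed a line break; sentence splitting treats these as sentence
#' boundaries in addition to terminal punctuation.
#'
#' @param text A character scalar (may be empty).
#' @param case_insensitive Lowercase the result? Default `TRUE`.
#'
#' @return The normalized string with attributes `offset_map` (integer) and
#'   `hard_breaks` (integer, possibly empty).
#' @examples
#' normalize_text("Acute  Decompensated\nHeart Failure")
#' @export
normalize_text <- function(text, case_insensitive = TRUE) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))

  # fast path: printable ASCII with single interior spaces needs only
  # trimming and lowercasing, and its offset map is the identity
  if (!grepl("[^ -~]", text, perl = TRUE) &&
      !grepl("  ", text, fixed = TRUE)) {
    first <- regexpr("[^ ]", text)
    if (first == -1L) {
      return(structure("", offset_map = integer(0), hard_breaks = integer(0)))
    }
    last <- nchar(text) - attr(regexpr(" *$", text), "match.length")
    out <- substr(text, first, last)
    if (case_insensitive) out <- tolower(out)
    return(structure(out, offset_map = seq.int(first, last),
                     hard_breaks = integer(0)))
  }

  chars <- strsplit(text, "", fixed = FALSE)[[1]]
  n <- length(chars)
  if (n == 0L) {
    return(structure("", offset_map = integer(0), hard_breaks = integer(0)))
  }

  dash_variants <- c(
    "‐", "‑", "‒", "–", "—", "―", "−"
  )
  single_quotes <- c("‘", "’", "‚", "‛", "′")
  double_quotes <- c("“", "”", "„", "‟", "″")

  chars[chars %in% dash_variants] <- "-"
  chars[chars %in% single_quotes] <- "'"
  chars[chars %in% double_quotes] <- "\""

  is_newline <- chars %in% c("\n", "\r", "\f", "\v")
  is_space <- grepl("^[\\s\u00a0]$", chars, perl = TRUE)
  chars[is_space] <- " "

  # collapse whitespace runs: keep the first space of each run; a run
  # containing a newline marks a hard sentence break at the kept space
  prev_space <- c(FALSE, is_space[-n])
  keep <- !(is_space & prev_space)
  # drop a leading space
  if (is_space[1L]) keep[1L] <- FALSE

  run_id <- cumsum(is_space & !prev_space)
  run_id[!is_space] <- 0L
  newline_runs <- unique(run_id[is_newline & is_space])

  kept_idx <- which(keep)
  out_chars <- chars[kept_idx]
  # drop a trailing space
  if (length(out_chars) && out_chars[length(out_chars)] == " ") {
    kept_idx <- kept_idx[-length(kept_idx)]
    out_chars <- out_chars[-length(out_chars)]
  }

  out <- paste0(out_chars, collapse = "")
  if (case_insensitive) out <- tolower(out)

  kept_runs <- run_id[kept_idx]
  hard_breaks <- which(kept_runs != 0L & kept_runs %in% newline_runs)

  structure(out, offset_map = kept_idx, hard_breaks = as.integer(hard_breaks))
}

# Sentence segmentation over a normalized string: boundaries are ., ;, !, ?
# (a period between two digits is a decimal point, not a boundary) plus the
# hard breaks recorded by normalize_text for original line breaks.
# Returns an integer sentence index (1-based) for every character position.
sentence_index_map <- function(norm) {
  n <- nchar(norm)
  if (n == 0L) return(integer(0))
  chars <- strsplit(norm, "", fixed = TRUE)[[1]]
  terminal <- chars %in% c(".", ";", "!", "?")
  if (any(terminal)) {
    dots <- which(chars == ".")
    if (length(dots)) {
      guard <- dots[dots > 1L & dots < n &
                      grepl("[0-9]", chars[pmax(dots - 1L, 1L)]) &
                      grepl("[0-9]", chars[pmin(dots + 1L, n)])]
      terminal[guard] <- FALSE
    }
  }
  boundary <- terminal
  hb <- attr(norm, "hard_breaks")
  if (length(hb)) boundary[hb] <- TRUE
  # sentence index increments after each boundary character
  idx <- cumsum(c(TRUE, boundary[-n]))
  # characters that are themselves boundaries belong to the sentence they end
  idx[boundary] <- cumsum(c(TRUE, boundary[-n]))[boundary]
  as.integer(idx)
}

# Token start positions (1-based, in normalized space): tokens are maximal
# runs of non-space characters. Used by window-scoped exclusion matching.
token_starts <- function(norm) {
  n <- nchar(norm)
  if (n == 0L) return(integer(0))
  chars <- strsplit(norm, "", fixed = TRUE)[[1]]
  nonspace <- chars != " "
  which(nonspace & c(TRUE, !nonspace[-n]))
}
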