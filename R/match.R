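#' Find inclusion-term matches in one note section
#'
#' Scans a section body for occurrences of the dictionary's inclusion
#' phrases. Matching runs in normalized space ([normalize_text()]), so case,
#' whitespace layout and typographic variants do not matter. Occurrences are
#' non-overlapping: at each position the longest matching phrase wins and
#' scanning resumes after its end. With `word_boundary` matching (the
#' default) a phrase only matches when it is not embedded in a longer
#' alphanumeric token, so `"adhf"` does not match inside `"BADHFX"`.
#'
#' Section scoping is the caller's job ([classify_admission()] only scans
#' sections whose name is in `dictionary$scoped_sections`); this function
#' scans whatever text it is given.
#'
#' @param text The section body (character scalar).
#' @param dictionary A [term_dictionary()].
#' @param section_name Canonical section name recorded on the matches.
#' @return A tibble of matches, ordered by position, with columns `term`,
#'   `section_name`, `start`, `end` (0-based half-open offsets into `text`),
#'   `sentence_index` (1-based), `suppressed_by` (`NA` until
#'   [apply_exclusions()] runs) and internal normalized-space offsets
#'   (`.norm_start`, `.norm_end`) used by exclusion scoping.
#' @examples
#' d <- term_dictionary("adhf", "rule out")
#' find_inclusion_matches("Admitted with ADHF.", d, "principal_diagnosis")
#' @export
find_inclusion_matches <- function(text, dictionary,
                                   section_name = NA_character_) {
  stopifnot(inherits(dictionary, "term_dictionary"))
  opts <- dictionary$match_options
  norm <- normalize_text(text, opts$case_insensitive)
  cand <- phrase_occurrences(norm, dictionary$inclusion_terms,
                             dict_norm_phrases(dictionary, "inclusion"),
                             opts$word_boundary)
  if (nrow(cand) == 0L) return(empty_match_table())

  # longest match at the leftmost position wins; resume after the match end
  cand <- cand[order(cand$start, -cand$len), , drop = FALSE]
  keep <- logical(nrow(cand))
  cursor <- 1L
  for (i in seq_len(nrow(cand))) {
    if (cand$start[i] >= cursor) {
      keep[i] <- TRUE
      cursor <- cand$start[i] + cand$len[i]
    }
  }
  cand <- cand[keep, , drop = FALSE]

  map <- attr(norm, "offset_map")
  sent <- sentence_index_map(norm)
  k <- nrow(cand)
  tibble::new_tibble(list(
    term = cand$term,
    section_name = rep(as.character(section_name), k),
    start = map[cand$start] - 1L,
    end = map[cand$start + cand$len - 1L],
    sentence_index = sent[cand$start],
    suppressed_by = rep(NA_character_, k),
    .norm_start = cand$start,
    .norm_end = cand$start + cand$len
  ), nrow = k)
}

# cached normalized phrase list, recomputed if the dictionary was edited
# by hand rather than rebuilt through term_dictionary()
dict_norm_phrases <- function(dictionary, which = c("inclusion", "exclusion")) {
  which <- match.arg(which)
  phrases <- dictionary[[paste0(which, "_terms")]]
  cached <- dictionary[[paste0("norm_", which)]]
  if (!is.null(cached) && length(cached) == length(phrases)) return(cached)
  vapply(phrases, function(p) {
    as.character(normalize_text(p, dictionary$match_options$case_insensitive))
  }, character(1), USE.NAMES = FALSE)
}

empty_match_table <- function() {
  tibble::new_tibble(list(
    term = character(0), section_name = character(0),
    start = integer(0), end = integer(0), sentence_index = integer(0),
    suppressed_by = character(0),
    .norm_start = integer(0), .norm_end = integer(0)
  ), nrow = 0L)
}

# All boundary-respecting occurrences of the phrases in the normalized
# string. `phrases` are the original dictionary phrases (reported on the
# match); `norm_phrases` their pre-normalized forms (searched for).
# Returns a data frame (term, start, len) in normalized coordinates, 1-based.
phrase_occurrences <- function(norm, phrases, norm_phrases, word_boundary) {
  n <- nchar(norm)
  out_term <- character(0); out_start <- integer(0); out_len <- integer(0)
  is_word <- NULL
  for (k in seq_along(norm_phrases)) {
    p <- norm_phrases[[k]]
    if (!nzchar(p) || n == 0L) next
    m <- gregexpr(p, norm, fixed = TRUE)[[1]]
    if (m[1L] == -1L) next
    starts <- as.integer(m)
    len <- nchar(p)
    if (word_boundary) {
      if (is.null(is_word)) {
        chars <- strsplit(norm, "", fixed = TRUE)[[1]]
        is_word <- grepl("[a-z0-9]", chars, ignore.case = TRUE)
      }
      ok_left <- starts == 1L | !is_word[pmax(starts - 1L, 1L)]
      ends <- starts + len - 1L
      ok_right <- ends == n | !is_word[pmin(ends + 1L, n)]
      starts <- starts[ok_left & ok_right]
    }
    if (length(starts)) {
      out_term <- c(out_term, rep(phrases[[k]], length(starts)))
      out_start <- c(out_start, starts)
      out_len <- c(out_len, rep(len, length(starts)))
    }
  }
  structure(list(term = out_term, start = out_start, len = out_len),
            class = "data.frame", row.names = c(NA, -length(out_term)))
}

#' Suppress matches in the scope of an exclusion cue
#'
#' Implements the exclusion-term rule of the phenotype: a hit is discarded
#' when a cue such as `"prior"`, `"rule out"` or `"negative for"` occurs in
#' its scope. Under `"sentence"` scoping (default) the scope is the sentence
#' containing the match (sentences split on `.`, `;`, `!`, `?` and line
#' breaks, with a decimal-number guard); under `"window"` scoping it is the
#' `window_tokens` tokens preceding the match. Surviving matches are
#' returned unmodified; suppressed matches get `suppressed_by` set to the
#' suppressing cue (the earliest cue in scope, ties to the longest).
#'
#' @param matches Matches from [find_inclusion_matches()] on the same `text`.
#' @param text The section body the matches were found in.
#' @param dictionary The same [term_dictionary()] used for matching.
#' @return The match tibble with `suppressed_by` filled in for suppressed
#'   rows.
#' @examples
#' d <- term_dictionary("adhf", c("prior", "rule out", "negative for"))
#' m <- find_inclusion_matches("Rule out ADHF.", d, "principal_diagnosis")
#' apply_exclusions(m, "Rule out ADHF.", d)
#' @export
apply_exclusions <- function(matches, text, dictionary) {
  stopifnot(inherits(dictionary, "term_dictionary"))
  if (nrow(matches) == 0L || length(dictionary$exclusion_terms) == 0L) {
    return(matches)
  }
  opts <- dictionary$match_options
  norm <- normalize_text(text, opts$case_insensitive)
  excl <- phrase_occurrences(norm, dictionary$exclusion_terms,
                             dict_norm_phrases(dictionary, "exclusion"),
                             opts$word_boundary)
  if (nrow(excl) == 0L) return(matches)
  # deterministic cue choice: earliest occurrence, then longest
  excl <- excl[order(excl$start, -excl$len), , drop = FALSE]

  if (opts$exclusion_scope == "sentence") {
    sent <- sentence_index_map(norm)
    excl$sentence <- sent[excl$start]
    for (i in seq_len(nrow(matches))) {
      in_scope <- excl$sentence == matches$sentence_index[i]
      if (any(in_scope)) {
        matches$suppressed_by[i] <- excl$term[which(in_scope)[1L]]
      }
    }
  } else {
    tok <- token_starts(norm)
    tok_of <- function(pos) findInterval(pos, tok)
    # distance counted from the last token of the cue: an adjacent match is
    # 1 token away, so window_tokens = k allows k - 1 intervening tokens
    excl$tok <- tok_of(excl$start + excl$len - 1L)
    for (i in seq_len(nrow(matches))) {
      mt <- tok_of(matches$.norm_start[i])
      dist <- mt - excl$tok
      in_scope <- excl$start < matches$.norm_start[i] &
        dist >= 1L & dist <= opts$window_tokens
      if (any(in_scope)) {
        matches$suppressed_by[i] <- excl$term[which(in_scope)[1L]]
      }
    }
  }
  matches
}
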