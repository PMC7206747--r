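# Independent brute-force oracle for the phenotype engine, written against
# the rule statement, not the engine: split each scoped section into
# sentences, lowercase and collapse whitespace, and call a sentence positive
# when it contains an inclusion phrase as a whole-token substring and no
# exclusion phrase. An admission is positive when any of its sentences is.
# Deliberately regex-based and sentence-first, unlike the engine's
# offset-mapped single-pass scan.

oracle_escape <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

oracle_phrase_in <- function(sentence, phrase) {
  pat <- paste0("(?<![a-z0-9])", oracle_escape(phrase), "(?![a-z0-9])")
  grepl(pat, sentence, perl = TRUE)
}

oracle_sentences <- function(text) {
  # protect decimal points, then split on terminal punctuation and newlines
  prot <- gsub("(?<=[0-9])\\.(?=[0-9])", "\x01", text, perl = TRUE)
  parts <- strsplit(prot, "[.;!?\n\r]", perl = TRUE)[[1]]
  parts <- gsub("\x01", ".", parts, fixed = TRUE)
  parts <- tolower(gsub("[[:space:]]+", " ", parts))
  trimws(parts)
}

oracle_classify_admission <- function(notes, dictionary) {
  inc <- tolower(gsub("[[:space:]]+", " ", dictionary$inclusion_terms))
  exc <- tolower(gsub("[[:space:]]+", " ", dictionary$exclusion_terms))
  for (note in notes) {
    sec <- note$sections
    sec <- sec[sec$name %in% dictionary$scoped_sections, , drop = FALSE]
    for (j in seq_len(nrow(sec))) {
      body <- substring(note$text, sec$start[j] + 1L, sec$end[j])
      for (sentence in oracle_sentences(body)) {
        if (!nzchar(sentence)) next
        has_inc <- any(vapply(inc, oracle_phrase_in,
                              logical(1), sentence = sentence))
        if (!has_inc) next
        has_exc <- length(exc) > 0 &&
          any(vapply(exc, oracle_phrase_in, logical(1), sentence = sentence))
        if (!has_exc) return(TRUE)
      }
    }
  }
  FALSE
}

oracle_classify_corpus <- function(notes, dictionary) {
  adm <- vapply(notes, function(x) x$admission_id, character(1))
  ids <- sort(unique(adm))
  stats::setNames(
    vapply(ids, function(id) {
      oracle_classify_admission(notes[adm == id], dictionary)
    }, logical(1)),
    ids
  )
}

# Clopper-Pearson oracle: invert the exact binomial tail tests numerically,
# without beta quantiles.
oracle_exact_ci <- function(k, n, alpha = 0.05) {
  low <- if (k == 0) 0 else {
    stats::uniroot(function(p) stats::pbinom(k - 1, n, p, lower.tail = FALSE) -
                     alpha / 2,
                   c(1e-12, 1 - 1e-12), tol = 1e-14)$root
  }
  high <- if (k == n) 1 else {
    stats::uniroot(function(p) stats::pbinom(k, n, p) - alpha / 2,
                   c(1e-12, 1 - 1e-12), tol = 1e-14)$root
  }
  c(low = low, high = high)
}
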