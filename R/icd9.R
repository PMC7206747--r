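#' ICD-9 code sets for heart-failure phenotyping
#'
#' A `code_set` pairs exact ICD-9-CM diagnosis codes with hierarchical
#' prefixes. An admission matches the set when any of its codes equals an
#' exact member or extends a prefix (e.g. prefix `"428"` matches `"428.0"`,
#' `"428.21"`, ...). Matching is exact-string on the dotted form, so
#' trailing zeros are significant: `"428.0"` and `"428.00"` are different
#' codes.
#'
#' @param name Label for the set (`"acute_hf"`, `"all_hf"`, or a custom
#'   label).
#' @param codes Character vector of exact codes (3 digits, optional decimal
#'   and 1-2 further digits).
#' @param prefixes Character vector of code prefixes matched hierarchically.
#' @return An object of class `code_set`.
#' @seealso [acute_hf_codes()], [all_hf_codes()], [load_code_set()].
#' @export
code_set <- function(name, codes = character(0), prefixes = character(0)) {
  codes <- unique(as.character(codes))
  prefixes <- unique(as.character(prefixes))
  if (length(codes) + length(prefixes) == 0L) {
    stop("a code set must contain at least one code or prefix", call. = FALSE)
  }
  bad <- c(codes[!is_valid_icd9(codes)], prefixes[!is_valid_icd9_prefix(prefixes)])
  if (length(bad)) {
    stop("syntactically invalid ICD-9 code(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(list(name = as.character(name), codes = codes, prefixes = prefixes),
            class = "code_set")
}

#' @export
print.code_set <- function(x, ...) {
  cat("<code_set ", x$name, "> ", length(x$codes), " exact code(s)",
      if (length(x$prefixes))
        paste0(", prefix(es): ", paste(x$prefixes, collapse = ", ")) else "",
      "\n", sep = "")
  invisible(x)
}

# ICD-9-CM diagnosis code syntax: 3 digits, optional decimal with 1-2 more
# digits; V and E codes also exist but the heart-failure family is numeric,
# so the numeric grammar is what admissions are validated against.
is_valid_icd9 <- function(code) {
  grepl("^[0-9]{3}(\\.[0-9]{1,2})?$", code) |
    grepl("^V[0-9]{2}(\\.[0-9]{1,2})?$", code) |
    grepl("^E[0-9]{3}(\\.[0-9])?$", code)
}

is_valid_icd9_prefix <- function(code) {
  is_valid_icd9(code) | grepl("^[0-9]{3}\\.$", code)
}

#' The acute heart-failure ICD-9 code set
#'
#' The 428-family codes whose fifth digit marks *acute* or *acute on
#' chronic* systolic, diastolic, or combined heart failure: 428.21, 428.23,
#' 428.31, 428.33, 428.41, 428.43. These are the codes that specifically
#' encode an acute decompensation, obtained from the heart-failure family by
#' excluding the chronic and unspecified codes.
#'
#' @return A `code_set` named `"acute_hf"`.
#' @export
acute_hf_codes <- function() {
  code_set("acute_hf",
           codes = c("428.21", "428.23", "428.31", "428.33",
                     "428.41", "428.43"))
}

#' The all-heart-failure ICD-9 code set
#'
#' Every code in the ICD-9 heart-failure family, via the hierarchical prefix
#' `428`. Hypertensive heart disease with heart failure (402.x1, 404.x1/x3)
#' is deliberately not included; add it with a custom [code_set()] if your
#' coding practice requires it.
#'
#' @return A `code_set` named `"all_hf"`.
#' @export
all_hf_codes <- function() {
  code_set("all_hf", prefixes = "428")
}

#' Classify an admission by its ICD-9 codes
#'
#' `TRUE` iff any syntactically valid code on the admission is an exact
#' member of the set or extends one of its prefixes. Invalid codes are
#' skipped with a warning. The result does not depend on code order.
#'
#' @param codes Character vector of ICD-9 codes for one admission (may be
#'   empty).
#' @param set A [code_set()].
#' @return Logical scalar.
#' @examples
#' classify_by_codes(c("401.9", "428.21"), acute_hf_codes())
#' classify_by_codes("428.22", acute_hf_codes())  # chronic systolic: FALSE
#' @export
classify_by_codes <- function(codes, set) {
  stopifnot(inherits(set, "code_set"))
  codes <- as.character(codes)
  codes <- codes[!is.na(codes) & nzchar(codes)]
  if (length(codes) == 0L) return(FALSE)
  valid <- is_valid_icd9(codes)
  if (any(!valid)) {
    warning("skipping syntactically invalid ICD-9 code(s): ",
            paste(unique(codes[!valid]), collapse = ", "), call. = FALSE)
    codes <- codes[valid]
  }
  if (length(codes) == 0L) return(FALSE)
  if (any(codes %in% set$codes)) return(TRUE)
  for (p in set$prefixes) {
    hit <- codes == p |
      startsWith(codes, paste0(p, ".")) |
      (grepl("\\.", p) & startsWith(codes, p))
    if (any(hit)) return(TRUE)
  }
  FALSE
}

#' Run an ICD-9 code strategy over a cohort of admissions
#'
#' @param admissions Tibble/data frame with `admission_id` and list-column
#'   `icd9_codes` (as from [read_icd9_codes()] or [generate_cohort()]).
#' @param set A [code_set()].
#' @return Named logical vector keyed by admission id (the prediction
#'   format the evaluation layer consumes).
#' @export
run_code_strategy <- function(admissions, set) {
  stats::setNames(
    vapply(admissions$icd9_codes, classify_by_codes, logical(1), set = set),
    admissions$admission_id
  )
}

#' Load a code set from CSV
#'
#' CSV with columns `code` and `kind` (`exact` or `prefix`); duplicate rows
#' collapse. A row with invalid code syntax is an error naming the row.
#'
#' @param path Path to the CSV.
#' @param name Label for the loaded set (default: file name without
#'   extension).
#' @return A [code_set()].
#' @export
load_code_set <- function(path, name = NULL) {
  if (!file.exists(path)) stop("code set file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character")
  if (!all(c("code", "kind") %in% names(df))) {
    stop("code set CSV must have columns code, kind", call. = FALSE)
  }
  bad_kind <- !df$kind %in% c("exact", "prefix")
  if (any(bad_kind)) {
    stop("row ", which(bad_kind)[1L], ": kind must be `exact` or `prefix`",
         call. = FALSE)
  }
  ok <- ifelse(df$kind == "prefix", is_valid_icd9_prefix(df$code),
               is_valid_icd9(df$code))
  if (any(!ok)) {
    stop("row ", which(!ok)[1L], ": invalid ICD-9 code syntax `",
         df$code[which(!ok)[1L]], "`", call. = FALSE)
  }
  code_set(
    name = name %||% tools::file_path_sans_ext(basename(path)),
    codes = df$code[df$kind == "exact"],
    prefixes = df$code[df$kind == "prefix"]
  )
}
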