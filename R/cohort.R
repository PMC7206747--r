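#' Apply the study eligibility flow to a patient cohort
#'
#' Reproduces the cohort funnel used to assemble the study population:
#' patients below the age threshold at the reference date are excluded
#' first, then (among adults) patients without research authorization, so
#' the two exclusion counts partition the excluded set. Age is computed in
#' whole years at the patient's first admission by default.
#'
#' @param patients Data frame with columns `patient_id`, `birth_date`
#'   (`Date`), `research_authorization` (logical).
#' @param admissions Data frame with columns `admission_id`, `patient_id`,
#'   `admit_date` (`Date`); every admission must reference a known patient.
#' @param min_age_years Minimum age in whole years (default 18).
#' @param require_authorization Exclude patients without research
#'   authorization? Default `TRUE`.
#' @param reference_date_rule How the age-reference date is chosen:
#'   `"first_admission"` (default) or `"last_admission"`.
#' @return A list with `eligible` (the eligible subset of `patients`) and
#'   `flow` (a `cohort_flow` object with the funnel counts).
#' @seealso [cohort_flow()] for the count arithmetic alone.
#' @export
filter_eligible <- function(patients, admissions,
                            min_age_years = 18,
                            require_authorization = TRUE,
                            reference_date_rule = c("first_admission",
                                                    "last_admission")) {
  reference_date_rule <- match.arg(reference_date_rule)
  stopifnot(min_age_years >= 0)
  unknown <- setdiff(admissions$patient_id, patients$patient_id)
  if (length(unknown)) {
    stop("admission(s) reference unknown patient(s): ",
         paste(utils::head(unknown, 5L), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(patients$patient_id)) {
    stop("duplicate patient_id in `patients`", call. = FALSE)
  }

  agg <- if (reference_date_rule == "first_admission") min else max
  ref_dates <- tapply(as.numeric(as.Date(admissions$admit_date)),
                      admissions$patient_id, agg)
  ref <- as.Date(ref_dates[patients$patient_id], origin = "1970-01-01")

  birth <- as.Date(patients$birth_date)
  if (any(!is.na(ref) & birth > ref)) {
    stop("birth_date after admission date for patient(s): ",
         paste(utils::head(
           patients$patient_id[!is.na(ref) & birth > ref], 5L),
           collapse = ", "), call. = FALSE)
  }
  age <- age_in_years(birth, ref)

  # patients with no admission have no reference date: never age-excluded
  too_young <- !is.na(age) & age < min_age_years
  no_auth <- require_authorization & !too_young &
    !patients$research_authorization

  flow <- cohort_flow(
    n_admissions = nrow(admissions),
    n_patients = nrow(patients),
    n_excluded_age = sum(too_young),
    n_excluded_auth = sum(no_auth)
  )
  list(eligible = patients[!too_young & !no_auth, , drop = FALSE], flow = flow)
}

# whole-year age at `ref`, i.e. number of completed birthdays
age_in_years <- function(birth, ref) {
  by <- as.integer(format(birth, "%Y"))
  ry <- as.integer(format(ref, "%Y"))
  years <- ry - by
  # subtract one if the birthday has not yet occurred in the reference year
  before_birthday <- format(ref, "%m%d") < format(birth, "%m%d")
  years - as.integer(before_birthday)
}

#' Cohort funnel counts
#'
#' Records the eligibility arithmetic: `n_eligible = n_patients -
#' n_excluded_age - n_excluded_auth`. Construction fails if any count is
#' negative or the identity cannot hold.
#'
#' @param n_admissions,n_patients,n_excluded_age,n_excluded_auth
#'   Non-negative integers.
#' @return An object of class `cohort_flow` with fields `n_admissions`,
#'   `n_patients`, `n_excluded_age`, `n_excluded_auth`, `n_eligible`.
#' @examples
#' cohort_flow(473146, 314988, 44867, 13678)  # n_eligible 256443
#' @export
cohort_flow <- function(n_admissions, n_patients, n_excluded_age,
                        n_excluded_auth) {
  counts <- c(n_admissions, n_patients, n_excluded_age, n_excluded_auth)
  if (any(counts < 0) || any(counts != trunc(counts))) {
    stop("cohort counts must be non-negative integers", call. = FALSE)
  }
  n_eligible <- n_patients - n_excluded_age - n_excluded_auth
  if (n_eligible < 0) {
    stop("exclusions exceed the patient count", call. = FALSE)
  }
  structure(
    list(n_admissions = as.integer(n_admissions),
         n_patients = as.integer(n_patients),
         n_excluded_age = as.integer(n_excluded_age),
         n_excluded_auth = as.integer(n_excluded_auth),
         n_eligible = as.integer(n_eligible)),
    class = "cohort_flow"
  )
}

#' @export
print.cohort_flow <- function(x, ...) {
  cat("<cohort_flow>\n")
  cat("  admissions:          ", format(x$n_admissions, big.mark = ","), "\n")
  cat("  patients:            ", format(x$n_patients, big.mark = ","), "\n")
  cat("  excluded (age):      ", format(x$n_excluded_age, big.mark = ","), "\n")
  cat("  excluded (no auth):  ", format(x$n_excluded_auth, big.mark = ","), "\n")
  cat("  eligible:            ", format(x$n_eligible, big.mark = ","), "\n")
  invisible(x)
}
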