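#' Derive death outcomes
#'
#' A patient is dead iff a death-registry record exists; the death is
#' disease-specific iff the primary cause is a bladder-cancer code (`C67*`
#' under ICD10 or `188*` under ICD9). An unparseable cause yields
#' `dead = TRUE, ubc_death = FALSE` with a warning.
#'
#' @param deaths Death records (`patient_id`, `death_date`,
#'   `primary_cause_icd`), at most one per patient.
#' @param patients Character vector of cohort patient ids.
#' @return data.table `patient_id`, `dead`, `ubc_death`, `death_date`.
#' @export
derive_death <- function(deaths, patients) {
  dd <- as.data.table(deaths)
  if (nrow(dd)) {
    if (anyDuplicated(dd$patient_id))
      stop_ubc("duplicate death record(s) for patient(s): %s",
               paste(unique(dd$patient_id[duplicated(dd$patient_id)]),
                     collapse = ", "))
    cause <- norm_icd(dd$primary_cause_icd)
    bad <- is.na(cause) | cause == "" | !grepl("^[A-Z0-9]", cause)
    if (any(bad))
      warn_ubc("%d death record(s) with unparseable cause: counted as non-UBC death",
               sum(bad))
    ubc <- !bad & (startsWith(cause, "C67") | startsWith(cause, "188"))
    dd <- dd[, .(patient_id, death_date = as.Date(death_date), ubc = ubc)]
  }
  out <- data.table(patient_id = patients)
  out <- merge(out, if (nrow(dd)) dd else
                 data.table(patient_id = character(),
                            death_date = as.Date(character()), ubc = logical()),
               by = "patient_id", all.x = TRUE)
  out[, `:=`(dead = !is.na(death_date), ubc_death = !is.na(ubc) & ubc)]
  out[, ubc := NULL]
  setcolorder(out, c("patient_id", "dead", "ubc_death", "death_date"))
  setorder(out, patient_id)
  out[]
}

#' Dichotomise age at a clinical cut-off
#'
#' The case group is `age >= cutoff` (boundary inclusive). Cut-offs other
#' than the standard 50/55/60/65/70 years are rejected unless explicitly
#' allowed.
#'
#' @param age Age(s) in years.
#' @param cutoff Cut-off in years.
#' @param allowed Permitted cut-offs; set `allow_any = TRUE` to bypass.
#' @param allow_any Accept any positive cut-off.
#' @return Logical vector, `TRUE` when `age >= cutoff`.
#' @export
dichotomize_age <- function(age, cutoff, allowed = c(50, 55, 60, 65, 70),
                            allow_any = FALSE) {
  if (!allow_any && !cutoff %in% allowed)
    stop_ubc("cutoff %s not in the configured set (%s)", cutoff,
             paste(allowed, collapse = ", "))
  age >= cutoff
}

#' Derive death and age outcome variables for a cohort
#'
#' Age at diagnosis is computed from full dates when a `birth_date` column is
#' present (difference / 365.25), otherwise as calendar-year difference from
#' `year_of_birth`.
#'
#' @param deaths Death records (see [derive_death()]).
#' @param samples Sample table (`patient_id`, `sex`, `year_of_birth`,
#'   `white_british_flag`, optionally `birth_date`).
#' @param index data.table `patient_id`, `index_date` from [select_cohort()].
#' @param cutoffs Age cut-offs to dichotomise at.
#' @return data.table with `patient_id`, `dead`, `ubc_death`,
#'   `age_at_diagnosis`, and one `age_ge_<cutoff>` logical column per cutoff.
#' @export
derive_outcomes <- function(deaths, samples, index,
                            cutoffs = c(50, 55, 60, 65, 70)) {
  idx <- normalise_index(index)
  sm <- as.data.table(samples)
  dth <- derive_death(deaths, idx$patient_id)
  out <- merge(idx, sm, by = "patient_id")
  if ("birth_date" %in% names(out)) {
    out[, age_at_diagnosis :=
          as.numeric(index_date - as.Date(birth_date)) / 365.25]
  } else {
    out[, age_at_diagnosis :=
          as.integer(format(index_date, "%Y")) - as.integer(year_of_birth)]
  }
  if (any(out$age_at_diagnosis <= 0, na.rm = TRUE))
    stop_ubc("non-positive age at diagnosis encountered")
  for (co in cutoffs)
    out[, paste0("age_ge_", co) := dichotomize_age(age_at_diagnosis, co,
                                                   allowed = cutoffs,
                                                   allow_any = TRUE)]
  out <- merge(out, dth[, .(patient_id, dead, ubc_death)], by = "patient_id")
  keep <- c("patient_id", "sex", "dead", "ubc_death", "age_at_diagnosis",
            paste0("age_ge_", cutoffs))
  setorder(out, patient_id)
  out[, ..keep][]
}
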