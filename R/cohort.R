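#' Cohort eligibility rules
#'
#' Diagnosis-code, histology and ancestry criteria defining the bladder
#' cancer cohort. ICD10 codes are matched at the listed 4-character
#' granularity after dot removal, with bare `C67` accepted as equivalent to
#' an unspecified-site bladder tumour (registry exports vary in specificity);
#' ICD9 and ICD-O morphology codes are matched exactly.
#'
#' @param icd10_codes,icd9_codes Character vectors of eligible diagnosis
#'   codes per ICD revision.
#' @param icdo_codes Eligible 4-digit ICD-O morphology (histology) codes.
#' @param require_white_british Restrict to patients whose precomputed
#'   White-British ancestry flag is TRUE (guards against population
#'   stratification; the flag is consumed, never derived here).
#' @return A list of class `eligibility_rules`.
#' @export
eligibility_rules <- function(
    icd10_codes = c("C67.0", "C67.1", "C67.2", "C67.3", "C67.4", "C67.5",
                    "C67.6", "C67.7", "C67.8", "C67.9", "D09.0"),
    icd9_codes = c("1880", "1882", "1884", "1886", "1888", "1889", "2337"),
    icdo_codes = c("8000", "8001", "8010", "8020", "8050", "8120", "8130"),
    require_white_british = TRUE) {
  if (!length(icd10_codes) || !length(icd9_codes) || !length(icdo_codes))
    stop_ubc("eligibility code sets must be non-empty")
  structure(list(icd10_codes = toupper(icd10_codes),
                 icd9_codes = as.character(icd9_codes),
                 icdo_codes = as.character(icdo_codes),
                 require_white_british = isTRUE(require_white_british)),
            class = "eligibility_rules")
}

norm_icd <- function(code) gsub(".", "", toupper(trimws(code)), fixed = TRUE)

#' Select the eligible bladder-cancer cohort
#'
#' A patient is eligible when at least one diagnosis record matches the code
#' list for its ICD revision, at least one record (same patient, any record)
#' carries an eligible histology, and the ancestry flag passes when required.
#' The index diagnosis is the earliest code-matching diagnosis date; patients
#' without genotype data are retained (genotype availability is handled per
#' variant at test time).
#'
#' @param diagnoses Validated diagnosis records (`patient_id`, `diag_date`,
#'   `icd_version`, `icd_code`, `icdo_histology`).
#' @param samples Sample table with `patient_id` and `white_british_flag`
#'   (only consulted when the rules require it).
#' @param rules An [eligibility_rules()].
#' @return List with `patients` (character vector) and `index` (data.table
#'   `patient_id`, `index_date`).
#' @export
select_cohort <- function(diagnoses, samples = NULL,
                          rules = eligibility_rules()) {
  dx <- as.data.table(diagnoses)
  need <- c("patient_id", "diag_date", "icd_version", "icd_code",
            "icdo_histology")
  if (!all(need %in% names(dx)))
    stop_ubc("diagnoses need columns %s", paste(need, collapse = ", "))
  dx[, diag_date := as.Date(diag_date)]

  set10 <- norm_icd(rules$icd10_codes)
  set9 <- norm_icd(rules$icd9_codes)
  code_n <- norm_icd(dx$icd_code)
  code_ok <- (dx$icd_version == 10L & (code_n %in% set10 | code_n == "C67")) |
             (dx$icd_version == 9L & code_n %in% set9)
  hist_ok <- as.character(dx$icdo_histology) %in% rules$icdo_codes

  pts_code <- unique(dx$patient_id[code_ok])
  pts_hist <- unique(dx$patient_id[hist_ok])
  eligible <- intersect(pts_code, pts_hist)

  if (rules$require_white_british) {
    if (is.null(samples))
      stop_ubc("samples table required when require_white_british is TRUE")
    sm <- as.data.table(samples)
    wb <- sm$patient_id[as.logical(sm$white_british_flag)]
    eligible <- intersect(eligible, wb)
  }
  dxe <- dx[code_ok & patient_id %in% eligible]
  idx <- if (nrow(dxe))
    dxe[, .(index_date = min(diag_date)), by = patient_id]
  else
    data.table(patient_id = character(), index_date = as.Date(character()))
  setorder(idx, patient_id)
  list(patients = sort(eligible), index = idx[])
}
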