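#' OPCS4 procedure-category map
#'
#' Maps OPCS4 procedure codes to the intervention categories used by the
#' event rules. Three-character entries match any four-character extension by
#' prefix (e.g. `M421` is a TURBT); four-character entries match exactly
#' (`M494` is intravesical chemotherapy, `M493` is not).
#'
#' @param TURBT,EXAM,IVC,CYSTECTOMY,RADIOTHERAPY,SYSTEMIC_CHEMO Character
#'   vectors of OPCS4 codes (3 or 4 characters).
#' @return A named list of class `code_map`.
#' @export
code_map <- function(TURBT = "M42",
                     EXAM = "M45",
                     IVC = c("M494", "M495"),
                     CYSTECTOMY = "M34",
                     RADIOTHERAPY = "X65",
                     SYSTEMIC_CHEMO = c("X72", "X292", "X298", "X308", "X352")) {
  map <- list(TURBT = TURBT, EXAM = EXAM, IVC = IVC, CYSTECTOMY = CYSTECTOMY,
              RADIOTHERAPY = RADIOTHERAPY, SYSTEMIC_CHEMO = SYSTEMIC_CHEMO)
  all_codes <- unlist(map, use.names = FALSE)
  if (!all(grepl("^[A-Z][0-9]{2,3}$", all_codes)))
    stop_ubc("OPCS4 codes must match ^[A-Z][0-9]{2,3}$")
  if (anyDuplicated(all_codes))
    stop_ubc("code map categories must be disjoint")
  structure(map, class = "code_map")
}

#' Temporal windows of the event rules
#'
#' All windows are in days and configurable; the defaults resolve the rule
#' wording "longer than 4 months" (120), "within 6 months" (183) and
#' ">3 months" (91).
#'
#' @param ivc_gap_days Gap between consecutive intravesical-chemotherapy
#'   episodes beyond which a new event is declared (strict `>`).
#' @param followup_window_days Look-forward window for examination-led events
#'   and for progression (inclusive, day 0 included).
#' @param independence_days Minimum separation for two events to count as
#'   independent (strict `>`).
#' @param baseline_window_days Events within this many days of the index
#'   diagnosis belong to the primary-treatment block.
#' @param invasiveness_window_days Look-forward from the index diagnosis for
#'   a cystectomy/radiotherapy to imply muscle invasion at baseline.
#' @return A list of class `window_config`.
#' @export
window_config <- function(ivc_gap_days = 120L, followup_window_days = 183L,
                          independence_days = 91L, baseline_window_days = 91L,
                          invasiveness_window_days = 183L) {
  w <- list(ivc_gap_days = as.integer(ivc_gap_days),
            followup_window_days = as.integer(followup_window_days),
            independence_days = as.integer(independence_days),
            baseline_window_days = as.integer(baseline_window_days),
            invasiveness_window_days = as.integer(invasiveness_window_days))
  if (any(unlist(w) <= 0L)) stop_ubc("all windows must be positive")
  structure(w, class = "window_config")
}

#' Classify hospital episodes into intervention categories
#'
#' @param episodes data.frame/data.table with columns `patient_id`,
#'   `episode_date` (Date) and `opcs4_code`.
#' @param map A [code_map()].
#' @param verbose Log uncategorised codes (dropped) via `message()`.
#' @return data.table with columns `patient_id`, `date`, `opcs4_code`,
#'   `category`, sorted by patient and date; uncategorised episodes removed.
#' @export
classify_episodes <- function(episodes, map = code_map(), verbose = FALSE) {
  ep <- as.data.table(episodes)
  if (!all(c("patient_id", "episode_date", "opcs4_code") %in% names(ep)))
    stop_ubc("episodes need columns patient_id, episode_date, opcs4_code")
  codes <- unlist(map, use.names = FALSE)
  cats <- rep(names(map), lengths(map))
  exact <- nchar(codes) == 4L
  # exact 4-char lookup first, then 3-char prefix lookup
  hit4 <- match(ep$opcs4_code, codes[exact])
  hit3 <- match(substr(ep$opcs4_code, 1L, 3L), codes[!exact])
  category <- ifelse(!is.na(hit4), cats[exact][hit4], cats[!exact][hit3])
  if (verbose && anyNA(category)) {
    dropped <- unique(ep$opcs4_code[is.na(category)])
    message("uncategorised OPCS4 codes dropped: ", paste(dropped, collapse = ", "))
  }
  out <- ep[!is.na(category),
            .(patient_id, date = as.Date(episode_date), opcs4_code)]
  out[, category := category[!is.na(category)]]
  setorder(out, patient_id, date, category)
  out[]
}

# categories that count as the "intervention" arm of the examination rule
RULE3_INTERVENTIONS <- c("IVC", "CYSTECTOMY", "RADIOTHERAPY", "SYSTEMIC_CHEMO")

# same-day candidate collapse order for deduplicate_events
RULE_PRIORITY <- c(TURBT_RULE = 1L, EXAM_RULE = 2L, IVC_GAP_RULE = 3L)

#' Derive candidate tumour events from categorised episodes
#'
#' Three rules generate candidate events:
#' \enumerate{
#'   \item every transurethral resection (TURBT) is an event at its date;
#'   \item within each patient's intravesical-chemotherapy sequence, a gap
#'     longer than `ivc_gap_days` between consecutive instillations starts a
#'     new event dated at the first instillation of the new block (the first
#'     block is treatment of a preceding event, not a new one);
#'   \item a bladder examination followed by an intravesical-chemotherapy,
#'     cystectomy, radiotherapy or systemic-chemotherapy episode within
#'     `followup_window_days` (day 0 inclusive) is an event at the
#'     examination date.
#' }
#'
#' @param cat_episodes Output of [classify_episodes()].
#' @param windows A [window_config()].
#' @return data.table `patient_id`, `date`, `rule` (TURBT_RULE /
#'   IVC_GAP_RULE / EXAM_RULE), sorted by patient and date.
#' @export
derive_candidate_events <- function(cat_episodes, windows = window_config()) {
  ep <- as.data.table(cat_episodes)
  empty <- data.table(patient_id = character(), date = as.Date(character()),
                      rule = character())
  if (!nrow(ep)) return(empty)
  setorder(ep, patient_id, date)

  r1 <- ep[category == "TURBT", .(patient_id, date, rule = "TURBT_RULE")]

  ivc <- ep[category == "IVC", .(patient_id, date)]
  setorder(ivc, patient_id, date)
  ivc[, gap := as.integer(date - shift(date)), by = patient_id]
  r2 <- ivc[!is.na(gap) & gap > windows$ivc_gap_days,
            .(patient_id, date, rule = "IVC_GAP_RULE")]

  ex <- ep[category == "EXAM", .(patient_id, date)]
  iv <- ep[category %in% RULE3_INTERVENTIONS, .(patient_id, date)]
  if (nrow(ex) && nrow(iv)) {
    ex[, `:=`(lo = date, hi = date + windows$followup_window_days)]
    iv[, date2 := date]
    hits <- iv[ex, on = .(patient_id, date2 >= lo, date2 <= hi), nomatch = NULL,
               .(patient_id, date = i.date)]
    r3 <- unique(hits)[, rule := "EXAM_RULE"]
  } else r3 <- empty
  out <- rbind(r1, r2, r3)
  setorder(out, patient_id, date, rule)
  out[]
}

# greedy left-anchored merge of a sorted integer date vector
greedy_keep <- function(days, gap) {
  keep <- logical(length(days))
  keep[1] <- TRUE
  last <- days[1]
  for (i in seq_along(days)[-1]) {
    if (days[i] - last > gap) {
      keep[i] <- TRUE
      last <- days[i]
    }
  }
  keep
}

#' Merge candidate events into independent events
#'
#' Greedy left-to-right pass per patient: an event within `independence_days`
#' of the previously retained event is absorbed into it (the earliest date,
#' and its rule, are kept). Retained dates are pairwise more than
#' `independence_days` apart.
#'
#' @param events Candidate events from [derive_candidate_events()].
#' @param windows A [window_config()].
#' @return data.table of retained events, same columns as the input.
#' @export
deduplicate_events <- function(events, windows = window_config()) {
  ev <- as.data.table(events)
  if (!nrow(ev)) return(ev)
  # same-day candidates collapse to one event; a same-day TURBT dominates an
  # examination which dominates an instillation-gap signal
  ev[, pri := RULE_PRIORITY[rule]]
  setorder(ev, patient_id, date, pri)
  ev <- unique(ev, by = c("patient_id", "date"))[, pri := NULL]
  ev[, keep := greedy_keep(as_days(date), windows$independence_days),
     by = patient_id]
  out <- ev[keep == TRUE][, keep := NULL]
  out[]
}

normalise_index <- function(index) {
  idx <- as.data.table(index)
  if (!all(c("patient_id", "index_date") %in% names(idx)))
    stop_ubc("index needs columns patient_id, index_date")
  idx[, .(patient_id, index_date = as.Date(index_date))]
}

#' Count recurrences per patient
#'
#' Independent events dated within `baseline_window_days` of the index
#' diagnosis form the primary-treatment block and are not counted; the
#' recurrence count is the number of independent events after that block.
#'
#' @param events Independent events from [deduplicate_events()].
#' @param index data.frame `patient_id`, `index_date` (one row per patient).
#' @param windows A [window_config()].
#' @return data.table `patient_id`, `recurrence_count`, `recurrence_flag`,
#'   `first_event_date` (first post-baseline event, NA if none), one row per
#'   index patient. Events for patients without an index date are skipped
#'   with a warning.
#' @export
call_recurrence <- function(events, index, windows = window_config()) {
  idx <- normalise_index(index)
  ev <- as.data.table(events)
  if (nrow(ev)) {
    orphan <- setdiff(ev$patient_id, idx$patient_id)
    if (length(orphan))
      warn_ubc("events for %d patient(s) without an index date skipped",
               length(orphan))
    ev <- merge(ev, idx, by = "patient_id")
    evp <- ev[as.integer(date - index_date) > windows$baseline_window_days]
    post <- if (nrow(evp))
      evp[, .(recurrence_count = .N, first_event_date = min(date)),
          by = patient_id]
    else
      data.table(patient_id = character(), recurrence_count = integer(),
                 first_event_date = as.Date(character()))
  } else {
    post <- data.table(patient_id = character(), recurrence_count = integer(),
                       first_event_date = as.Date(character()))
  }
  out <- merge(idx[, .(patient_id)], post, by = "patient_id", all.x = TRUE)
  out[is.na(recurrence_count), recurrence_count := 0L]
  out[, recurrence_flag := recurrence_count >= 1L]
  setorder(out, patient_id)
  out[]
}

#' Flag disease progression per patient
#'
#' Progression is called when a post-baseline independent event generated by
#' the TURBT or examination rule is followed by a cystectomy or radiotherapy
#' episode within `followup_window_days` (day 0 inclusive). Every progression
#' is by construction also a recurrence.
#'
#' @param events Independent events from [deduplicate_events()].
#' @param cat_episodes Output of [classify_episodes()] (source of the
#'   cystectomy / radiotherapy episodes).
#' @param index data.frame `patient_id`, `index_date`.
#' @param windows A [window_config()].
#' @return data.table `patient_id`, `progression_flag` (one row per index
#'   patient).
#' @export
call_progression <- function(events, cat_episodes, index,
                             windows = window_config()) {
  idx <- normalise_index(index)
  ev <- as.data.table(events)
  ep <- as.data.table(cat_episodes)
  prog <- character()
  if (nrow(ev)) {
    ev <- merge(ev, idx, by = "patient_id")
    cand <- ev[rule %in% c("TURBT_RULE", "EXAM_RULE") &
                 as.integer(date - index_date) > windows$baseline_window_days,
               .(patient_id, date)]
    rad <- ep[category %in% c("CYSTECTOMY", "RADIOTHERAPY"),
              .(patient_id, date)]
    if (nrow(cand) && nrow(rad)) {
      cand[, `:=`(lo = date, hi = date + windows$followup_window_days)]
      rad[, date2 := date]
      hit <- rad[cand, on = .(patient_id, date2 >= lo, date2 <= hi),
                 nomatch = NULL]
      prog <- unique(hit$patient_id)
    }
  }
  out <- idx[, .(patient_id, progression_flag = patient_id %in% prog)]
  setorder(out, patient_id)
  out[]
}

#' Classify baseline invasiveness (MIBC vs NMIBC)
#'
#' A cystectomy or radiotherapy episode within `invasiveness_window_days`
#' after the index diagnosis (day 0 inclusive) marks the cancer as
#' muscle-invasive at baseline; otherwise it is non-muscle-invasive.
#'
#' @inheritParams call_progression
#' @return data.table `patient_id`, `mibc_at_baseline` (logical).
#' @export
classify_invasiveness <- function(cat_episodes, index,
                                  windows = window_config()) {
  idx <- normalise_index(index)
  ep <- as.data.table(cat_episodes)
  mibc <- character()
  rad <- ep[category %in% c("CYSTECTOMY", "RADIOTHERAPY"), .(patient_id, date)]
  if (nrow(rad)) {
    rad <- merge(rad, idx, by = "patient_id")
    d <- rad[, as.integer(date - index_date)]
    mibc <- unique(rad$patient_id[d >= 0L & d <= windows$invasiveness_window_days])
  }
  out <- idx[, .(patient_id, mibc_at_baseline = patient_id %in% mibc)]
  setorder(out, patient_id)
  out[]
}

#' Derive all procedure-based phenotypes for a cohort
#'
#' Runs episode classification, candidate-event derivation, independence
#' merging, recurrence counting, progression and baseline-invasiveness calls,
#' and asserts the invariant that progression implies recurrence.
#'
#' @param episodes Raw episode records (`patient_id`, `episode_date`,
#'   `opcs4_code`).
#' @param index data.frame `patient_id`, `index_date` from [select_cohort()].
#' @param map A [code_map()].
#' @param windows A [window_config()].
#' @return List with `phenotypes` (one row per index patient: recurrence
#'   count/flag, progression flag, MIBC flag, first post-baseline event date)
#'   and `events` (the per-patient independent-event audit trail).
#' @export
derive_phenotypes <- function(episodes, index, map = code_map(),
                              windows = window_config()) {
  idx <- normalise_index(index)
  cat_ep <- classify_episodes(episodes, map)
  cat_ep <- cat_ep[patient_id %in% idx$patient_id]
  cand <- derive_candidate_events(cat_ep, windows)
  ev <- deduplicate_events(cand, windows)
  rec <- call_recurrence(ev, idx, windows)
  prog <- call_progression(ev, cat_ep, idx, windows)
  inv <- classify_invasiveness(cat_ep, idx, windows)
  ph <- Reduce(function(a, b) merge(a, b, by = "patient_id"),
               list(rec, prog, inv))
  # progression implies recurrence by construction; enforce and verify
  bad <- ph[progression_flag & !recurrence_flag]
  if (nrow(bad)) {
    warn_ubc("%d progression call(s) without recurrence; recurrence forced",
             nrow(bad))
    ph[progression_flag & !recurrence_flag,
       `:=`(recurrence_flag = TRUE, recurrence_count = pmax(recurrence_count, 1L))]
  }
  stopifnot(all(!ph$progression_flag | ph$recurrence_flag))
  setcolorder(ph, c("patient_id", "recurrence_count", "recurrence_flag",
                    "progression_flag", "mibc_at_baseline", "first_event_date"))
  list(phenotypes = ph[], events = ev)
}
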