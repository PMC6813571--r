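# Brute-force reference implementations of the event rules, written as plain
# per-code / per-pair loops with no shared code with the package internals.
# Streams are (day, category) pairs for one patient; the index diagnosis is
# day 0 unless stated.

ORACLE_CATS <- c("TURBT", "EXAM", "IVC", "CYSTECTOMY", "RADIOTHERAPY",
                 "SYSTEMIC_CHEMO")

oracle_classify_one <- function(code, map) {
  for (cat in names(map)) {
    for (entry in map[[cat]]) {
      hit <- if (nchar(entry) == 4L) identical(code, entry)
             else identical(substr(code, 1, 3), entry)
      if (hit) return(cat)
    }
  }
  NA_character_
}

# candidate events: data.frame(day, rule), possibly with duplicates removed
# per (day) later by the dedup oracle
oracle_candidates <- function(day, cat, w) {
  ev_day <- integer(); ev_rule <- character()
  for (i in seq_along(day)) {
    if (cat[i] == "TURBT") {
      ev_day <- c(ev_day, day[i]); ev_rule <- c(ev_rule, "TURBT_RULE")
    }
  }
  ivc <- sort(day[cat == "IVC"])
  if (length(ivc) >= 2) {
    for (i in 2:length(ivc)) {
      if (ivc[i] - ivc[i - 1] > w$ivc_gap_days) {
        ev_day <- c(ev_day, ivc[i]); ev_rule <- c(ev_rule, "IVC_GAP_RULE")
      }
    }
  }
  inter <- day[cat %in% c("IVC", "CYSTECTOMY", "RADIOTHERAPY", "SYSTEMIC_CHEMO")]
  for (d in day[cat == "EXAM"]) {
    if (any(inter >= d & inter <= d + w$followup_window_days)) {
      ev_day <- c(ev_day, d); ev_rule <- c(ev_rule, "EXAM_RULE")
    }
  }
  data.frame(day = ev_day, rule = ev_rule, stringsAsFactors = FALSE)
}

# collapse same-day candidates with TURBT > EXAM > IVC_GAP priority, then
# recursively build the minimal left-anchored covering set
oracle_dedup <- function(cand, gap) {
  if (!nrow(cand)) return(cand)
  pri <- c(TURBT_RULE = 1, EXAM_RULE = 2, IVC_GAP_RULE = 3)
  cand <- cand[order(cand$day, pri[cand$rule]), , drop = FALSE]
  cand <- cand[!duplicated(cand$day), , drop = FALSE]
  keep <- cand[1, , drop = FALSE]
  rest <- cand[cand$day - keep$day[1] > gap, , drop = FALSE]
  rbind(keep, oracle_dedup(rest, gap))
}

oracle_phenotype <- function(day, cat, w, index_day = 0L) {
  cand <- oracle_candidates(day, cat, w)
  kept <- oracle_dedup(cand, w$independence_days)
  post <- kept[kept$day - index_day > w$baseline_window_days, , drop = FALSE]
  rec_count <- nrow(post)
  radical <- day[cat %in% c("CYSTECTOMY", "RADIOTHERAPY")]
  prog <- FALSE
  for (i in seq_len(nrow(post))) {
    if (post$rule[i] %in% c("TURBT_RULE", "EXAM_RULE") &&
        any(radical >= post$day[i] &
            radical <= post$day[i] + w$followup_window_days))
      prog <- TRUE
  }
  mibc <- any(radical >= index_day &
              radical <= index_day + w$invasiveness_window_days)
  list(kept = kept, recurrence_count = rec_count,
       recurrence = rec_count >= 1, progression = prog, mibc = mibc)
}

# random (day, category) stream on a date grid
random_stream <- function(n_ep, grid, cats = ORACLE_CATS) {
  list(day = sample(grid, n_ep, replace = TRUE),
       cat = sample(cats, n_ep, replace = TRUE))
}

# enumerate all category/date multisets of exactly `size` episodes
enumerate_streams <- function(size, grid, cats = ORACLE_CATS) {
  symbols <- expand.grid(day = grid, cat = cats, stringsAsFactors = FALSE)
  ns <- nrow(symbols)
  out <- list()
  rec <- function(start, picked) {
    if (length(picked) == size) {
      out[[length(out) + 1L]] <<- list(day = symbols$day[picked],
                                       cat = symbols$cat[picked])
      return(invisible())
    }
    for (i in start:ns) rec(i, c(picked, i))
  }
  if (size > 0) rec(1L, integer()) else out <- list(list(day = integer(),
                                                         cat = character()))
  out
}

# run the package pipeline on a batch of single-patient streams (episodes
# expressed as real codes realising each category) and return per-stream
# phenotype rows; origin fixes day-0 as a calendar date
CAT_TO_CODE <- c(TURBT = "M421", EXAM = "M451", IVC = "M494",
                 CYSTECTOMY = "M341", RADIOTHERAPY = "X651",
                 SYSTEMIC_CHEMO = "X298")

streams_to_tables <- function(streams, origin = as.Date("2000-01-01")) {
  pid <- sprintf("S%05d", seq_along(streams))
  n_ep <- vapply(streams, function(s) length(s$day), 1L)
  episodes <- data.frame(
    patient_id = rep(pid, n_ep),
    episode_date = origin + unlist(lapply(streams, `[[`, "day")),
    opcs4_code = unname(CAT_TO_CODE[unlist(lapply(streams, `[[`, "cat"))]),
    stringsAsFactors = FALSE)
  index <- data.frame(patient_id = pid, index_date = origin,
                      stringsAsFactors = FALSE)
  list(episodes = episodes, index = index, pid = pid)
}

expect_streams_match_oracle <- function(streams, w = window_config()) {
  tb <- streams_to_tables(streams)
  ph <- derive_phenotypes(tb$episodes, tb$index, windows = w)$phenotypes
  ph <- ph[match(tb$pid, ph$patient_id), ]
  orc <- lapply(streams, function(s) oracle_phenotype(s$day, s$cat, w))
  expect_equal(ph$recurrence_count,
               vapply(orc, `[[`, 1L, "recurrence_count"),
               ignore_attr = TRUE)
  expect_equal(ph$progression_flag, vapply(orc, `[[`, TRUE, "progression"),
               ignore_attr = TRUE)
  expect_equal(ph$mibc_at_baseline, vapply(orc, `[[`, TRUE, "mibc"),
               ignore_attr = TRUE)
  invisible(NULL)
}
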