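#' Synthetic-cohort configuration
#'
#' Defaults restate the descriptive profile of the cohort the pipeline is
#' designed for: roughly 1,500 bladder-cancer patients, 78\% male, age at
#' diagnosis about N(61, 9^2) years, 40.3\% with a recurrence, 3.8\% with a
#' progression, 7.4\% muscle-invasive at baseline, 13.6\% deaths of which
#' half are disease-specific (6.9\% of the cohort), with index diagnoses
#' spread uniformly over 1997--2010 (the coverage window of admitted
#' in-patient episode data).
#'
#' @param n_patients Number of eligible patients to simulate.
#' @param prop_male Fraction of males.
#' @param age_mean,age_sd Age-at-diagnosis distribution (years).
#' @param recurrence_rate Fraction of patients with >= 1 recurrence.
#' @param progression_rate Fraction with a progression (must be
#'   `<= recurrence_rate`; progressors are drawn among recurrers).
#' @param mibc_rate Fraction muscle-invasive at baseline.
#' @param death_rate,ubc_death_rate Fractions dead / dead of bladder cancer
#'   (`ubc_death_rate <= death_rate`).
#' @param prop_ineligible Fraction of additional contaminant patients carrying
#'   an ineligible histology (appended beyond `n_patients`).
#' @param exam_rate Fraction of event-free patients receiving a surveillance
#'   cystoscopy that must not trigger any rule.
#' @param noise_code_rate Fraction of patients with an uncategorised
#'   procedure code in their stream.
#' @param variants List of variant descriptors, each a list/vector with
#'   fields `rsid`, `allele_ref`, `allele_eff`, `maf` in (0, 0.5],
#'   `odds_ratio` > 0 and `outcome_label` (see [read_catalog()] for labels).
#' @param prob_noise Dispersion of genotype-probability triples around the
#'   true genotype in `[0, 1]` (0 = hard calls, INFO 1).
#' @param index_start,index_end Bounds of the index-diagnosis dates.
#' @param seed Integer seed; all outputs are deterministic given it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 1500, prop_male = 0.78,
                       age_mean = 61, age_sd = 9,
                       recurrence_rate = 0.403, progression_rate = 0.038,
                       mibc_rate = 0.074, death_rate = 0.136,
                       ubc_death_rate = 0.069, prop_ineligible = 0,
                       exam_rate = 0.3, noise_code_rate = 0.5,
                       variants = list(), prob_noise = 0,
                       index_start = "1997-01-01", index_end = "2010-12-31",
                       seed = 1L) {
  rates <- c(prop_male = prop_male, recurrence_rate = recurrence_rate,
             progression_rate = progression_rate, mibc_rate = mibc_rate,
             death_rate = death_rate, ubc_death_rate = ubc_death_rate,
             prop_ineligible = prop_ineligible, exam_rate = exam_rate,
             noise_code_rate = noise_code_rate, prob_noise = prob_noise)
  if (any(rates < 0 | rates > 1))
    stop_ubc("all rates must lie in [0,1]; offending: %s",
             paste(names(rates)[rates < 0 | rates > 1], collapse = ", "))
  if (progression_rate > recurrence_rate)
    stop_ubc("progression_rate must be <= recurrence_rate")
  if (ubc_death_rate > death_rate)
    stop_ubc("ubc_death_rate must be <= death_rate")
  if (n_patients < 1) stop_ubc("n_patients must be positive")
  for (v in variants) {
    v <- as.list(v)
    if (!(as.numeric(v$maf) > 0 && as.numeric(v$maf) <= 0.5))
      stop_ubc("variant %s: maf must be in (0, 0.5]", v$rsid)
    if (as.numeric(v$odds_ratio) <= 0)
      stop_ubc("variant %s: odds_ratio must be > 0", v$rsid)
  }
  structure(list(n_patients = as.integer(n_patients), prop_male = prop_male,
                 age_mean = age_mean, age_sd = age_sd,
                 recurrence_rate = recurrence_rate,
                 progression_rate = progression_rate, mibc_rate = mibc_rate,
                 death_rate = death_rate, ubc_death_rate = ubc_death_rate,
                 prop_ineligible = prop_ineligible, exam_rate = exam_rate,
                 noise_code_rate = noise_code_rate, variants = variants,
                 prob_noise = prob_noise,
                 index_start = as.Date(index_start),
                 index_end = as.Date(index_end), seed = as.integer(seed)),
            class = "sim_config")
}

# draw one Dirichlet vector concentrated on component `g+1`
rdirichlet_geno <- function(g, noise) {
  if (noise == 0) {
    p <- c(0, 0, 0); p[g + 1L] <- 1
    return(p)
  }
  alpha <- rep(noise, 3)
  alpha[g + 1L] <- alpha[g + 1L] + 1 / noise
  x <- rgamma(3, shape = alpha)
  x / sum(x)
}

#' Simulate genotypes for a binary outcome under an additive model
#'
#' Retrospective case-control sampling: control genotypes are
#' Binomial(2, maf); case genotypes use the allele frequency tilted on the
#' logit scale by the per-allele log odds ratio
#' (`logit(p_case) = logit(maf) + log(OR)`), with Hardy-Weinberg genotype
#' frequencies within each group. Probability triples are symmetric-Dirichlet
#' perturbations centred on the true genotype; the dosage is the expected
#' allele count from the triple, so dosage and triple are always consistent.
#'
#' @param outcome Logical/0-1 case indicator per patient.
#' @param maf Population (control) effect-allele frequency in (0, 0.5].
#' @param odds_ratio Per-allele odds ratio, > 0.
#' @param prob_noise Dirichlet dispersion in `[0, 1]`; 0 gives hard calls.
#' @param seed Optional integer seed (omit to use the current RNG stream).
#' @param rsid,allele_ref,allele_eff Variant annotation carried through.
#' @return A list of class `variant_data` with fields `rsid`, `allele_ref`,
#'   `allele_eff`, `dosage`, `prob` (n x 3 matrix), `info`, `maf`.
#' @export
simulate_genotypes <- function(outcome, maf, odds_ratio, prob_noise = 0,
                               seed = NULL, rsid = "rs0",
                               allele_ref = "A", allele_eff = "G") {
  if (!(maf > 0 && maf <= 0.5)) stop_ubc("maf must be in (0, 0.5]")
  if (odds_ratio <= 0) stop_ubc("odds_ratio must be > 0")
  if (!is.null(seed)) set.seed(as.integer(seed))
  y <- as.logical(outcome)
  n <- length(y)
  p_case <- plogis(qlogis(maf) + log(odds_ratio))
  g <- integer(n)
  g[!y] <- rbinom(sum(!y), 2L, maf)
  g[y] <- rbinom(sum(y), 2L, p_case)
  prob <- t(vapply(g, rdirichlet_geno, numeric(3), noise = prob_noise))
  dosage <- prob[, 2] + 2 * prob[, 3]
  structure(list(rsid = rsid, allele_ref = allele_ref,
                 allele_eff = allele_eff, dosage = dosage, prob = prob,
                 info = info_score(prob),
                 maf = maf_from_counts(sum(prob[, 1]), sum(prob[, 2]),
                                       sum(prob[, 3]))),
            class = "variant_data")
}

# ---------------------------------------------------------------------------
# Episode-stream construction: codes are written through the *inverse* of the
# event rules, so the phenotyping engine recovers the ground-truth labels
# exactly. Layout per patient (day offsets from the index diagnosis):
#   +7    TURBT (primary treatment; baseline block, never counted)
#   +30   cystectomy/radiotherapy iff truly MIBC (inside the baseline and
#         invasiveness windows, outside any progression pairing)
#   t_j = 200 + 250 (j-1) + U{-40..40}   true recurrence events, realised as
#         a TURBT, a new intravesical-chemo block (gap > 120 d), or an
#         examination followed by systemic chemotherapy at t_j + 30
#   t_k + 60   cystectomy or radiotherapy iff truly progressing (within the
#         6-month pairing window of the final event, > 183 d after index)
# Spacings guarantee: event gaps > independence window (91 d), IVC gaps
# > 120 d, and no accidental examination-rule or invasiveness triggers.
# ---------------------------------------------------------------------------

sim_patient_episodes <- function(pid, truth_row, cfg) {
  days <- integer(); codes <- character()
  add <- function(d, code) {
    days <<- c(days, d); codes <<- c(codes, code)
  }
  add(7L, sample(c("M421", "M422", "M428"), 1L))
  if (truth_row$mibc)
    add(30L, sample(c("M342", "X651"), 1L))
  k <- truth_row$recurrence_count
  if (k > 0L) {
    t <- 200L + 250L * (seq_len(k) - 1L) + sample(-40:40, k, replace = TRUE)
    rules <- sample(c("TURBT", "IVC", "EXAM"), k, replace = TRUE,
                    prob = c(0.5, 0.25, 0.25))
    if (truth_row$progression) rules[k] <- "TURBT"
    if (any(rules == "IVC")) add(14L, "M494")  # anchor block: prior treatment
    for (j in seq_len(k)) {
      switch(rules[j],
             TURBT = add(t[j], sample(c("M421", "M429"), 1L)),
             IVC = add(t[j], sample(c("M494", "M495"), 1L)),
             EXAM = {
               add(t[j], "M451")
               add(t[j] + 30L, "X721")  # systemic chemo completes the rule
             })
    }
    if (truth_row$progression)
      add(t[k] + 60L, sample(c("M342", "X651"), 1L))
  } else if (runif(1) < cfg$exam_rate) {
    add(400L, "M451")  # surveillance cystoscopy; no intervention follows
  }
  if (runif(1) < cfg$noise_code_rate)
    add(sample(30:1000, 1L), sample(c("A011", "E852", "W371", "K634"), 1L))
  list(days = days, codes = codes)
}

#' Simulate a full synthetic cohort with embedded ground truth
#'
#' Generates cancer-registry diagnoses, hospital-episode streams, death
#' records, a sample table, and genotypes for the configured variants. The
#' episode streams are constructed through the inverse of the phenotyping
#' rules so that [derive_phenotypes()] recovers the ground-truth labels
#' exactly (a failure of that round trip indicates a rule-engine defect, not
#' simulator noise). Contaminant patients with ineligible histology can be
#' appended to exercise cohort selection.
#'
#' @param config A [sim_config()].
#' @return List of class `sim_cohort` with data.tables `registry`,
#'   `episodes`, `deaths`, `samples`, a list `genotypes` of `variant_data`
#'   (one per configured variant), and `truth` (per-patient ground-truth
#'   labels: eligibility, recurrence count, progression, MIBC, death cause,
#'   age).
#' @export
simulate_cohort <- function(config = sim_config()) {
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_patients
  n_bad <- as.integer(round(n * cfg$prop_ineligible))
  n_all <- n + n_bad
  pid <- sprintf("P%05d", seq_len(n_all))
  eligible <- c(rep(TRUE, n), rep(FALSE, n_bad))

  sex <- ifelse(runif(n_all) < cfg$prop_male, "M", "F")
  index_date <- cfg$index_start +
    floor(runif(n_all) * (as.integer(cfg$index_end - cfg$index_start) + 1))
  age <- pmin(pmax(round(rnorm(n_all, cfg$age_mean, cfg$age_sd)), 30), 95)
  yob <- as.integer(format(index_date, "%Y")) - age

  recur <- runif(n_all) < cfg$recurrence_rate
  p_prog <- if (cfg$recurrence_rate > 0)
    cfg$progression_rate / cfg$recurrence_rate else 0
  prog <- recur & runif(n_all) < p_prog
  rec_count <- integer(n_all)
  rec_count[recur] <- 1L + rpois(sum(recur), 0.5)
  mibc <- runif(n_all) < cfg$mibc_rate
  dead <- runif(n_all) < cfg$death_rate
  p_ubc <- if (cfg$death_rate > 0) cfg$ubc_death_rate / cfg$death_rate else 0
  ubc_death <- dead & runif(n_all) < p_ubc

  truth <- data.table(patient_id = pid, eligible = eligible, sex = sex,
                      age = age, recurrence_count = rec_count,
                      recurrence = recur, progression = prog, mibc = mibc,
                      dead = dead, ubc_death = ubc_death,
                      index_date = index_date)

  # registry: one eligible (or contaminant) diagnosis at the index date
  icd_ver <- ifelse(runif(n_all) < 0.9, 10L, 9L)
  icd_code <- ifelse(icd_ver == 10L,
                     sample(sprintf("C67.%d", 0:9), n_all, replace = TRUE),
                     sample(c("1880", "1882", "1884", "1886", "1888", "1889",
                              "2337"), n_all, replace = TRUE))
  hist_ok <- sample(c("8000", "8001", "8010", "8020", "8050", "8120", "8130"),
                    n_all, replace = TRUE, prob = c(rep(0.04, 5), 0.5, 0.3))
  hist_bad <- sample(c("8140", "8070", "8980"), n_all, replace = TRUE)
  registry <- data.table(patient_id = pid, diag_date = index_date,
                         icd_version = icd_ver, icd_code = icd_code,
                         icdo_histology = ifelse(eligible, hist_ok, hist_bad))

  ep_list <- lapply(seq_len(n_all), function(i)
    sim_patient_episodes(pid[i], truth[i], cfg))
  episodes <- data.table(
    patient_id = rep(pid, vapply(ep_list, function(e) length(e$days), 1L)),
    episode_date = index_date[rep(seq_len(n_all),
                                  vapply(ep_list, function(e) length(e$days), 1L))] +
      unlist(lapply(ep_list, `[[`, "days")),
    opcs4_code = unlist(lapply(ep_list, `[[`, "codes")))
  setorder(episodes, patient_id, episode_date, opcs4_code)

  deaths <- data.table(
    patient_id = pid[dead],
    death_date = index_date[dead] + sample(365:6000, sum(dead), replace = TRUE),
    primary_cause_icd = ifelse(ubc_death[dead], "C67.9",
                               sample(c("I21.9", "J44.9", "C34.9", "I64"),
                                      sum(dead), replace = TRUE)))

  samples <- data.table(patient_id = pid, sex = sex, year_of_birth = yob,
                        white_british_flag = TRUE)

  genotypes <- list()
  for (v in cfg$variants) {
    v <- as.list(v)
    yv <- outcome_vector(as.character(v$outcome_label), truth)
    genotypes[[v$rsid]] <- simulate_genotypes(
      yv, as.numeric(v$maf), as.numeric(v$odds_ratio),
      prob_noise = cfg$prob_noise, rsid = as.character(v$rsid),
      allele_ref = as.character(v$allele_ref %||% "A"),
      allele_eff = as.character(v$allele_eff %||% "G"))
    genotypes[[v$rsid]]$dosage <- stats::setNames(genotypes[[v$rsid]]$dosage, pid)
  }

  structure(list(registry = registry, episodes = episodes, deaths = deaths,
                 samples = samples, genotypes = genotypes, truth = truth,
                 config = cfg),
            class = "sim_cohort")
}

# ground-truth outcome vector for a catalog outcome label
outcome_vector <- function(label, truth) {
  switch(label,
         recurrence = truth$recurrence,
         progression = truth$progression,
         overall_survival = truth$dead,
         ubc_specific_survival = truth$ubc_death,
         age_continuous = truth$age >= stats::median(truth$age),
         {
           m <- regmatches(label, regexec("^age_cutoff_(\\d+)$", label))[[1]]
           if (length(m) == 2L) truth$age >= as.numeric(m[2])
           else stop_ubc("unknown outcome_label '%s'", label)
         })
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf(
    "synthetic UBC cohort: %d patients (%d eligible), %d episodes, %d deaths, %d variant(s)\n",
    nrow(x$samples), sum(x$truth$eligible), nrow(x$episodes), nrow(x$deaths),
    length(x$genotypes)))
  invisible(x)
}
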