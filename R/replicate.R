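outcome_family <- function(label) {
  ifelse(label %in% c("overall_survival", "ubc_specific_survival"), "survival",
         ifelse(startsWith(label, "age"), "age", label))
}

#' Percentage of a count within a total
#'
#' @param count,n Numerator and denominator counts.
#' @return `100 * count / n` (unrounded).
#' @export
percent <- function(count, n) {
  if (any(n <= 0)) stop_ubc("n must be positive")
  100 * count / n
}

strand_ambiguous <- function(a1, a2) {
  pair <- paste(sort(c(toupper(a1), toupper(a2))), collapse = "/")
  pair %in% c("A/T", "C/G")
}

# harmonise the file's effect allele with the catalog's; returns the sign to
# apply to beta ("flip"), plus a status flag
harmonise_alleles <- function(entry, variant) {
  if (is.na(variant$allele_ref) || is.na(variant$allele_eff))
    return(list(sign = 1, status = "alleles_assumed"))
  if (strand_ambiguous(variant$allele_ref, variant$allele_eff))
    return(list(sign = 1, status = "strand_ambiguous"))
  if (entry$allele_eff == variant$allele_eff &&
      entry$allele_ref == variant$allele_ref)
    return(list(sign = 1, status = "ok"))
  if (entry$allele_eff == variant$allele_ref &&
      entry$allele_ref == variant$allele_eff)
    return(list(sign = -1, status = "flipped"))
  list(sign = NA_real_, status = "allele_mismatch")
}

subgroup_mask <- function(subgroup, phenotypes) {
  switch(subgroup,
         UBC = rep(TRUE, nrow(phenotypes)),
         NMIBC = !phenotypes$mibc_at_baseline,
         MIBC = phenotypes$mibc_at_baseline,
         stop_ubc("unknown subgroup '%s'", subgroup))
}

replication_outcome <- function(label, phenotypes, outcomes) {
  switch(label,
         recurrence = phenotypes$recurrence_flag,
         progression = phenotypes$progression_flag,
         overall_survival = outcomes$dead,
         ubc_specific_survival = outcomes$ubc_death,
         age_continuous = outcomes$age_at_diagnosis,
         {
           col <- sub("age_cutoff_", "age_ge_", label)
           if (!col %in% names(outcomes))
             stop_ubc("unknown outcome_label '%s'", label)
           outcomes[[col]]
         })
}

empty_assoc_row <- function(entry, status) {
  data.table(rsid = entry$rsid, outcome_label = entry$outcome_label,
             subgroup = entry$subgroup,
             family_label = outcome_family(entry$outcome_label),
             allele_ref = NA_character_, allele_eff = NA_character_,
             info = NA_real_, n_total = NA_real_, n_cases = NA_real_,
             n_controls = NA_real_,
             maf_all = NA_real_, maf_cases = NA_real_, maf_controls = NA_real_,
             triple_all = NA_character_, triple_cases = NA_character_,
             triple_controls = NA_character_,
             beta = NA_real_, se = NA_real_, or = NA_real_,
             ci_lower = NA_real_, ci_upper = NA_real_, p_value = NA_real_,
             log10_bf = NA_real_, converged = NA, status = status,
             low_n = NA, nominal_significant = NA, bonferroni_significant = NA,
             direction_consistent = NA)
}

fmt_triple <- function(tri) {
  paste(vapply(tri, function(x)
    formatC(round(x, 2), format = "fg", digits = 8), character(1)),
    collapse = "/")
}

assoc_one_entry <- function(entry, variant, phenotypes, outcomes, sexcov,
                            acfg, min_cases) {
  harm <- harmonise_alleles(entry, variant)
  if (identical(harm$status, "allele_mismatch"))
    return(empty_assoc_row(entry, "allele_mismatch"))

  mask <- subgroup_mask(entry$subgroup, phenotypes)
  ids <- phenotypes$patient_id[mask]
  y <- replication_outcome(entry$outcome_label, phenotypes, outcomes)[mask]
  g <- variant$dosage[ids]
  sx <- sexcov[ids]
  ok <- !is.na(g) & !is.na(y)
  y <- y[ok]; g <- g[ok]; sx <- sx[ok]; ids <- ids[ok]
  linear <- entry$outcome_label == "age_continuous"

  prob <- variant$prob
  if (!is.null(prob)) {
    rows <- match(ids, names(variant$dosage))
    prob <- prob[rows, , drop = FALSE]
  }
  ymask <- if (linear) rep(TRUE, length(y)) else as.logical(y)
  tri <- tryCatch(
    genotype_count_triples(prob = prob,
                           dosage = if (is.null(prob)) g else NULL,
                           case_mask = ymask),
    error = function(e) NULL)

  fit <- tryCatch({
    if (linear) fit_linear_dosage(y, g, covariates = cbind(sex = sx),
                                  config = acfg)
    else fit_logistic_dosage(y, g, covariates = cbind(sex = sx),
                             config = acfg)
  }, error = function(e) e)
  if (inherits(fit, "error")) {
    row <- empty_assoc_row(entry, paste0("fit_failed: ", conditionMessage(fit)))
    row$n_total <- length(y)
    row$n_cases <- if (linear) NA_real_ else sum(y)
    row$n_controls <- if (linear) NA_real_ else sum(!y)
    return(row)
  }
  beta <- harm$sign * fit$beta
  q <- qnorm(1 - (1 - acfg$ci_level) / 2)
  n_cases <- if (linear) NA_real_ else sum(y)
  data.table(
    rsid = entry$rsid, outcome_label = entry$outcome_label,
    subgroup = entry$subgroup,
    family_label = outcome_family(entry$outcome_label),
    allele_ref = variant$allele_ref, allele_eff = variant$allele_eff,
    info = variant$info, n_total = length(y), n_cases = n_cases,
    n_controls = if (linear) NA_real_ else sum(!y),
    maf_all = if (!is.null(tri)) maf_from_counts(tri$all[1], tri$all[2],
                                                 tri$all[3]) else NA_real_,
    maf_cases = if (!is.null(tri) && !linear && sum(tri$cases) > 0)
      maf_from_counts(tri$cases[1], tri$cases[2], tri$cases[3]) else NA_real_,
    maf_controls = if (!is.null(tri) && !linear && sum(tri$controls) > 0)
      maf_from_counts(tri$controls[1], tri$controls[2], tri$controls[3])
      else NA_real_,
    triple_all = if (!is.null(tri)) fmt_triple(tri$all) else NA_character_,
    triple_cases = if (!is.null(tri) && !linear) fmt_triple(tri$cases)
                   else NA_character_,
    triple_controls = if (!is.null(tri) && !linear) fmt_triple(tri$controls)
                      else NA_character_,
    beta = beta, se = fit$se,
    or = if (linear) NA_real_ else exp(beta),
    ci_lower = if (linear) beta - q * fit$se else exp(beta - q * fit$se),
    ci_upper = if (linear) beta + q * fit$se else exp(beta + q * fit$se),
    p_value = fit$p,
    log10_bf = log10_abf(beta, fit$se, acfg$abf_prior_sd),
    converged = if (linear) TRUE else fit$converged,
    status = harm$status,
    low_n = if (linear) length(y) < min_cases else
      min(sum(y), sum(!y)) < min_cases,
    nominal_significant = NA, bonferroni_significant = NA,
    direction_consistent =
      if (entry$original_effect_direction %in% c("+", "-"))
        (beta > 0) == (entry$original_effect_direction == "+") else NA)
}

#' Descriptive cohort summary
#'
#' Table-1-style counts and percentages for sex, death, disease-specific
#' death, recurrence, progression and baseline invasiveness, plus mean (SD)
#' age. The chi-square column is a one-sample goodness-of-fit statistic of
#' the binary split against equal 50/50 proportions, `(yes - no)^2 / n` on
#' 1 degree of freedom (an interpretation of a per-variable test; it is not
#' a two-way independence test).
#'
#' @param phenotypes Phenotype table from [derive_phenotypes()].
#' @param outcomes Outcome table from [derive_outcomes()].
#' @return data.table with one row per variable level (count, percent) and
#'   per-variable chi-square statistic and p-value; the age row carries the
#'   mean and SD instead of a count.
#' @export
descriptive_table <- function(phenotypes, outcomes) {
  ph <- as.data.table(phenotypes)
  oc <- as.data.table(outcomes)
  n <- nrow(ph)
  stopifnot(n == nrow(oc))
  bin <- list(
    Sex = oc$sex == "M",
    Death = oc$dead,
    `UBC-specific death` = oc$ubc_death,
    Recurrence = ph$recurrence_flag,
    Progression = ph$progression_flag,
    `NMIBC at baseline` = !ph$mibc_at_baseline)
  rows <- lapply(names(bin), function(v) {
    yes <- sum(bin[[v]]); no <- n - yes
    stat <- (yes - no)^2 / n
    data.table(variable = v,
               level = c("Yes", "No"),
               count = c(yes, no),
               percent = percent(c(yes, no), n),
               chisq_stat = stat,
               chisq_p = pchisq(stat, df = 1, lower.tail = FALSE))
  })
  age_row <- data.table(variable = "Age", level = "Mean (SD)",
                        count = NA_real_, percent = NA_real_,
                        chisq_stat = NA_real_, chisq_p = NA_real_)
  out <- rbind(rbindlist(rows), age_row)
  out[variable == "Sex", level := c("Male", "Female")]
  attr(out, "n") <- n
  attr(out, "age_mean") <- mean(oc$age_at_diagnosis)
  attr(out, "age_sd") <- sd(oc$age_at_diagnosis)
  out[]
}

#' Run the end-to-end candidate-SNP replication pipeline
#'
#' Cohort selection, procedure-based phenotyping, death/age outcome
#' derivation, then one dosage regression per catalog entry restricted to
#' the entry's subgroup (UBC = whole cohort; NMIBC / MIBC by baseline
#' invasiveness) and outcome, adjusted for sex, with approximate Bayes
#' factor, nominal and per-outcome Bonferroni significance, and
#' direction-consistency versus the original report. Rows are sorted by
#' p-value within outcome family; a catalog rsID absent from the genotype
#' data yields a `missing_variant` row, so the report always has one row per
#' catalog entry.
#'
#' @param registry,episodes,deaths,samples Validated record tables (see
#'   [read_records()]).
#' @param genotypes Named list of `variant_data` (see [read_genotypes()]).
#' @param catalog Catalog table (see [read_catalog()]).
#' @param config Optional named list overriding components: `rules`
#'   ([eligibility_rules()]), `map` ([code_map()]), `windows`
#'   ([window_config()]), `assoc` ([assoc_config()]), `min_cases`
#'   (low-sample flag threshold, default 10).
#' @return Object of class `replication_report`: list with `results` (one
#'   row per catalog entry), `descriptive`, `phenotypes`, `outcomes`,
#'   `events` (audit trail), `thresholds` (per-family Bonferroni levels) and
#'   `cohort`.
#' @export
run_replication <- function(registry, episodes, deaths, samples, genotypes,
                            catalog, config = list()) {
  rules <- config$rules %||% eligibility_rules()
  map <- config$map %||% code_map()
  windows <- config$windows %||% window_config()
  acfg <- config$assoc %||% assoc_config()
  min_cases <- config$min_cases %||% 10L

  sel <- select_cohort(registry, samples, rules)
  ph <- derive_phenotypes(episodes, sel$index, map, windows)
  oc <- derive_outcomes(deaths, samples, sel$index)
  phe <- ph$phenotypes[match(oc$patient_id, patient_id)]
  stopifnot(identical(phe$patient_id, oc$patient_id))
  sexcov <- stats::setNames(as.numeric(oc$sex == "M"), oc$patient_id)

  cat_dt <- as.data.table(catalog)
  fam_sizes <- if (nrow(cat_dt))
    table(outcome_family(cat_dt$outcome_label)) else table(character())
  thresholds <- vapply(fam_sizes, function(m)
    bonferroni_alpha(acfg$alpha, m), numeric(1))

  rows <- lapply(seq_len(nrow(cat_dt)), function(i) {
    entry <- as.list(cat_dt[i])
    variant <- genotypes[[entry$rsid]]
    if (is.null(variant)) return(empty_assoc_row(entry, "missing_variant"))
    assoc_one_entry(entry, variant, phe, oc, sexcov, acfg, min_cases)
  })
  results <- if (length(rows)) rbindlist(rows) else
    empty_assoc_row(list(rsid = NA, outcome_label = "recurrence",
                         subgroup = "UBC"), "empty")[0]
  if (nrow(results)) {
    results[, nominal_significant := !is.na(p_value) & p_value < acfg$alpha]
    results[, bonferroni_significant := !is.na(p_value) &
              p_value < thresholds[family_label]]
    setorder(results, family_label, p_value, na.last = TRUE)
  }
  structure(list(results = results,
                 descriptive = descriptive_table(phe, oc),
                 phenotypes = phe, outcomes = oc, events = ph$events,
                 thresholds = thresholds, cohort = sel),
            class = "replication_report")
}

#' @export
print.replication_report <- function(x, ...) {
  d <- x$descriptive
  cat(sprintf("replication report: %d patients, %d catalog entries\n",
              attr(d, "n"), nrow(x$results)))
  cat(sprintf("  age %.1f (%.1f); recurrence %.1f%%; progression %.1f%%; NMIBC %.1f%%\n",
              attr(d, "age_mean"), attr(d, "age_sd"),
              d[variable == "Recurrence" & level == "Yes", percent],
              d[variable == "Progression" & level == "Yes", percent],
              d[variable == "NMIBC at baseline" & level == "Yes", percent]))
  if (nrow(x$results)) {
    sig <- x$results[nominal_significant == TRUE]
    cat(sprintf("  %d/%d entries nominally significant (p < 0.05), %d after Bonferroni\n",
                nrow(sig), nrow(x$results),
                sum(x$results$bonferroni_significant, na.rm = TRUE)))
  }
  invisible(x)
}

#' Write the report tables of a replication run
#'
#' @param report A `replication_report`.
#' @param dir Output directory.
#' @return Invisibly, the paths written (report, descriptive, phenotypes,
#'   events audit log).
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(report = file.path(dir, "report.csv"),
             descriptive = file.path(dir, "descriptive.csv"),
             phenotypes = file.path(dir, "phenotypes.csv"),
             events = file.path(dir, "events.csv"))
  fwrite(report$results, paths["report"])
  desc <- copy(report$descriptive)
  desc[variable == "Age",
       level := sprintf("%.1f (%.1f)", attr(report$descriptive, "age_mean"),
                        attr(report$descriptive, "age_sd"))]
  fwrite(desc, paths["descriptive"])
  fwrite(report$phenotypes, paths["phenotypes"])
  fwrite(report$events, paths["events"])
  invisible(paths)
}
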