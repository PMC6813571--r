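sim_with_variants <- function(n = 600, seed = 37, variants = NULL) {
  if (is.null(variants))
    variants <- list(list(rsid = "rs1", allele_ref = "T", allele_eff = "G",
                          maf = 0.3, odds_ratio = 1.6,
                          outcome_label = "recurrence"))
  simulate_cohort(sim_config(n_patients = n, seed = seed, variants = variants))
}

test_that("subgroup restriction sizes the analysis correctly", {
  sim <- sim_with_variants()
  cat <- rbind(make_catalog("rs1", "recurrence", subgroup = "UBC",
                            allele_ref = "T", allele_eff = "G"),
               make_catalog("rs1", "recurrence", subgroup = "NMIBC",
                            allele_ref = "T", allele_eff = "G"),
               make_catalog("rs1", "recurrence", subgroup = "MIBC",
                            allele_ref = "T", allele_eff = "G"))
  rep <- run_replication(sim$registry, sim$episodes, sim$deaths, sim$samples,
                         sim$genotypes, cat)
  res <- rep$results
  n_ubc <- res$n_total[res$subgroup == "UBC"]
  n_nm <- res$n_total[res$subgroup == "NMIBC"]
  n_mi <- res$n_total[res$subgroup == "MIBC"]
  expect_equal(n_ubc, nrow(rep$phenotypes))
  expect_equal(n_nm + n_mi, n_ubc)  # NMIBC + MIBC partition the cohort
  expect_equal(n_mi, sum(rep$phenotypes$mibc_at_baseline))
  expect_true(all(res$low_n[res$subgroup == "MIBC"] |
                    res$n_cases[res$subgroup == "MIBC"] >= 10))
})

test_that("empty catalog yields a descriptive-only report", {
  sim <- sim_with_variants(n = 150)
  cat0 <- make_catalog(character(), character())
  rep <- run_replication(sim$registry, sim$episodes, sim$deaths, sim$samples,
                         sim$genotypes, cat0)
  expect_equal(nrow(rep$results), 0L)
  expect_gt(nrow(rep$descriptive), 0L)
})

test_that("report has one row per catalog entry, missing variants included", {
  sim <- sim_with_variants(n = 200, seed = 41)
  cat <- rbind(make_catalog("rs1", "recurrence", allele_ref = "T",
                            allele_eff = "G"),
               make_catalog("rs_missing", "progression"))
  rep <- run_replication(sim$registry, sim$episodes, sim$deaths, sim$samples,
                         sim$genotypes, cat)
  expect_equal(nrow(rep$results), 2L)
  expect_equal(rep$results$status[rep$results$rsid == "rs_missing"],
               "missing_variant")
  # bonferroni implies nominal; thresholds derive from catalog family sizes
  ok <- rep$results[!is.na(rep$results$p_value), ]
  expect_true(all(!ok$bonferroni_significant | ok$nominal_significant))
  expect_equal(unname(rep$thresholds["recurrence"]), 0.05)
  expect_equal(unname(rep$thresholds["progression"]), 0.05)
})

test_that("per-outcome thresholds follow the loaded catalog's family sizes", {
  sim <- sim_with_variants(n = 150, seed = 43)
  cat <- make_full_catalog()
  cat$rsid[1] <- "rs1"; cat$allele_ref[1] <- "T"; cat$allele_eff[1] <- "G"
  rep <- suppressWarnings(
    run_replication(sim$registry, sim$episodes, sim$deaths, sim$samples,
                    sim$genotypes, cat))
  expect_equal(unname(rep$thresholds[c("recurrence", "survival", "age",
                                       "progression")]),
               0.05 / c(69, 53, 20, 23))
  expect_equal(nrow(rep$results), nrow(cat))
})

test_that("allele harmonisation flips the effect and flags ambiguity", {
  set.seed(47)
  y <- rbinom(4000, 1, 0.4)
  v <- simulate_genotypes(y, maf = 0.3, odds_ratio = 1.5, rsid = "rsX",
                          allele_ref = "T", allele_eff = "G")
  fit <- fit_logistic_dosage(y, v$dosage)
  sim <- sim_with_variants(n = 100, seed = 49)
  # entry lists the same variant with ref/eff swapped: beta must flip sign
  entries <- list(
    same = make_catalog("rsX", "recurrence", allele_ref = "T", allele_eff = "G"),
    swap = make_catalog("rsX", "recurrence", allele_ref = "G", allele_eff = "T"))
  ph <- data.table::data.table(patient_id = names(v$dosage) <-
                                 sprintf("P%05d", seq_along(v$dosage)),
                               recurrence_flag = y == 1,
                               progression_flag = FALSE,
                               mibc_at_baseline = FALSE)
  oc <- data.table::data.table(patient_id = ph$patient_id, sex = "M",
                               dead = FALSE, ubc_death = FALSE,
                               age_at_diagnosis = 60)
  sexcov <- stats::setNames(rep(1, nrow(ph)), ph$patient_id)
  r_same <- ubcphen:::assoc_one_entry(as.list(entries$same[1, ]), v, ph, oc,
                                      sexcov, assoc_config(), 10)
  r_swap <- ubcphen:::assoc_one_entry(as.list(entries$swap[1, ]), v, ph, oc,
                                      sexcov, assoc_config(), 10)
  expect_equal(r_same$status, "ok")
  expect_equal(r_swap$status, "flipped")
  expect_equal(r_swap$beta, -r_same$beta, tolerance = 1e-12)
  # strand-ambiguous alleles are flagged, not flipped
  v$allele_ref <- "A"; v$allele_eff <- "T"
  amb <- make_catalog("rsX", "recurrence", allele_ref = "A", allele_eff = "T")
  r_amb <- ubcphen:::assoc_one_entry(as.list(amb[1, ]), v, ph, oc, sexcov,
                                     assoc_config(), 10)
  expect_equal(r_amb$status, "strand_ambiguous")
})

test_that("a true signal outranks null variants by p-value", {
  hits <- 0L
  n_seeds <- 20
  for (seed in seq_len(n_seeds)) {
    vars <- c(list(list(rsid = "rs_true", allele_ref = "T", allele_eff = "G",
                        maf = 0.3, odds_ratio = 1.5,
                        outcome_label = "recurrence")),
              lapply(1:9, function(i)
                list(rsid = paste0("rs_null", i), allele_ref = "A",
                     allele_eff = "G", maf = 0.3, odds_ratio = 1,
                     outcome_label = "recurrence")))
    sim <- simulate_cohort(sim_config(n_patients = 2000, seed = 1000 + seed,
                                      variants = vars))
    cat <- make_catalog(c("rs_true", paste0("rs_null", 1:9)), "recurrence",
                        allele_ref = c("T", rep("A", 9)), allele_eff = "G")
    rep <- run_replication(sim$registry, sim$episodes, sim$deaths,
                           sim$samples, sim$genotypes, cat)
    best <- rep$results$rsid[which.min(rep$results$p_value)]
    hits <- hits + (best == "rs_true")
  }
  # OR 1.5 at n=2000 vs 9 nulls: the true variant should rank first nearly
  # always (>= 95% of seeds; one miss allowed at 20 runs)
  expect_gte(hits, 19L)
})

test_that("descriptive table reproduces brute-force percentages", {
  sim <- sim_with_variants(n = 400, seed = 53)
  rep <- run_replication(sim$registry, sim$episodes, sim$deaths, sim$samples,
                         sim$genotypes,
                         make_catalog(character(), character()))
  d <- rep$descriptive
  ph <- rep$phenotypes
  expect_equal(d$count[d$variable == "Recurrence" & d$level == "Yes"],
               sum(ph$recurrence_flag))
  expect_equal(d$percent[d$variable == "Recurrence" & d$level == "Yes"],
               100 * sum(ph$recurrence_flag) / nrow(ph))
  expect_equal(d$count[d$variable == "NMIBC at baseline" & d$level == "Yes"],
               sum(!ph$mibc_at_baseline))
  # chi-square GOF vs 50/50: (yes-no)^2/n, zero-event cohort gives stat = n
  yes <- sum(ph$progression_flag); n <- nrow(ph)
  expect_equal(d$chisq_stat[d$variable == "Progression"][1],
               (yes - (n - yes))^2 / n)
  d0 <- descriptive_table(
    data.frame(patient_id = "P1", recurrence_flag = FALSE,
               progression_flag = FALSE, mibc_at_baseline = FALSE),
    data.frame(patient_id = "P1", sex = "M", dead = FALSE, ubc_death = FALSE,
               age_at_diagnosis = 60))
  expect_equal(d0$percent[d0$variable == "Recurrence"], c(0, 100))
})

test_that("re-running on identical inputs is byte-identical", {
  sim <- sim_with_variants(n = 150, seed = 59)
  cat <- make_catalog("rs1", "recurrence", allele_ref = "T", allele_eff = "G")
  r1 <- run_replication(sim$registry, sim$episodes, sim$deaths, sim$samples,
                        sim$genotypes, cat)
  r2 <- run_replication(sim$registry, sim$episodes, sim$deaths, sim$samples,
                        sim$genotypes, cat)
  d1 <- tempfile(); d2 <- tempfile()
  write_report(r1, d1); write_report(r2, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
})

test_that("CLI runs simulate and the full pipeline end to end", {
  d <- file.path(tempfile(), "run")
  catf <- system.file("extdata", "example_catalog.csv", package = "ubcphen")
  # small-n MIBC subgroups may emit designed non-convergence warnings
  suppressWarnings(suppressMessages(
    ubcphen_cli(c("all", paste0("--out=", d), "--seed=3", "--n=250",
                  paste0("--catalog=", catf), "--quiet=TRUE"))))
  expect_true(file.exists(file.path(d, "report.csv")))
  rep <- data.table::fread(file.path(d, "report.csv"))
  expect_equal(nrow(rep), 8L)
  expect_true(file.exists(file.path(d, "phenotypes.csv")))
  expect_true(file.exists(file.path(d, "descriptive.csv")))
})
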