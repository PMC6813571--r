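# small in-code fixture builders shared across test files

make_episodes <- function(pid, days, codes, origin = as.Date("2000-01-01")) {
  data.frame(patient_id = pid, episode_date = origin + days,
             opcs4_code = codes, stringsAsFactors = FALSE)
}

make_index <- function(pid, origin = as.Date("2000-01-01")) {
  data.frame(patient_id = unique(pid), index_date = origin,
             stringsAsFactors = FALSE)
}

make_catalog <- function(rsid, outcome_label, subgroup = "UBC",
                         allele_ref = "A", allele_eff = "G",
                         direction = "+", estimate = 1.5) {
  n <- length(rsid)
  data.frame(rsid = rsid, allele_ref = rep_len(allele_ref, n),
             allele_eff = rep_len(allele_eff, n),
             outcome_label = rep_len(outcome_label, n),
             subgroup = rep_len(subgroup, n),
             original_effect_direction = rep_len(direction, n),
             original_estimate = rep_len(estimate, n),
             stringsAsFactors = FALSE)
}

# catalog with the per-family sizes of the shipped replication lists
make_full_catalog <- function() {
  fam <- c(recurrence = 69, survival = 53, age = 20, progression = 23)
  labels <- c(rep("recurrence", 69),
              rep(c("overall_survival", "ubc_specific_survival"), c(40, 13)),
              rep(c("age_continuous", "age_cutoff_60", "age_cutoff_65"),
                  c(10, 5, 5)),
              rep("progression", 23))
  make_catalog(rsid = sprintf("rs%06d", seq_along(labels)),
               outcome_label = labels)
}

expand_triple <- function(tri) {
  rep(0:2, times = tri)
}

# printed genotype-count triples for the worked replication examples
RS2042329 <- list(all = c(255, 739, 540), cases = c(88, 284, 246),
                  controls = c(167, 455, 294))
RS2344673_CASES <- c(24, 2, 0)
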