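RECORD_SCHEMAS <- list(
  diagnosis = c("patient_id", "diag_date", "icd_version", "icd_code",
                "icdo_histology"),
  episode = c("patient_id", "episode_date", "opcs4_code"),
  death = c("patient_id", "death_date", "primary_cause_icd"),
  sample = c("patient_id", "sex", "year_of_birth", "white_british_flag")
)

OUTCOME_LABELS <- c("recurrence", "progression", "overall_survival",
                    "ubc_specific_survival", "age_continuous",
                    paste0("age_cutoff_", c(50, 55, 60, 65, 70)))
SUBGROUPS <- c("UBC", "NMIBC", "MIBC")

parse_iso_date <- function(x, what, rows) {
  d <- as.Date(as.character(x), format = "%Y-%m-%d")
  bad <- which(is.na(d) & !is.na(x) & x != "")
  if (length(bad) || anyNA(d))
    stop_ubc("%s: unparseable ISO-8601 date at row(s) %s", what,
             paste(utils::head(rows[c(bad, which(is.na(x) | x == ""))], 5),
                   collapse = ", "))
  d
}

#' Read and validate typed record files
#'
#' CSV readers for the four record types consumed by the pipeline. The
#' reader is total: every row either parses against the schema or the call
#' fails with a message naming the offending row(s); nothing is silently
#' dropped.
#'
#' @param path CSV file (comma-separated, UTF-8, ISO-8601 dates).
#' @param kind One of `"diagnosis"`, `"episode"`, `"death"`, `"sample"`.
#' @return data.table of validated records (possibly zero rows).
#' @export
read_records <- function(path, kind = c("diagnosis", "episode", "death",
                                        "sample")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop_ubc("file not found: %s", path)
  schema <- RECORD_SCHEMAS[[kind]]
  dt <- fread(path, colClasses = "character", header = TRUE)
  if (!identical(names(dt), schema))
    stop_ubc("%s: header must be exactly (%s)", path,
             paste(schema, collapse = ", "))
  if (!nrow(dt)) {
    out <- switch(kind,
      diagnosis = data.table(patient_id = character(),
                             diag_date = as.Date(character()),
                             icd_version = integer(), icd_code = character(),
                             icdo_histology = character()),
      episode = data.table(patient_id = character(),
                           episode_date = as.Date(character()),
                           opcs4_code = character()),
      death = data.table(patient_id = character(),
                         death_date = as.Date(character()),
                         primary_cause_icd = character()),
      sample = data.table(patient_id = character(), sex = character(),
                          year_of_birth = integer(),
                          white_british_flag = logical()))
    return(out)
  }
  rows <- seq_len(nrow(dt)) + 1L  # 1-based file rows incl. header
  if (any(dt$patient_id == "" | is.na(dt$patient_id)))
    stop_ubc("%s: empty patient_id at row(s) %s", kind,
             paste(utils::head(rows[dt$patient_id == ""], 5), collapse = ", "))
  if (kind == "diagnosis") {
    ver <- suppressWarnings(as.integer(dt$icd_version))
    bad <- which(is.na(ver) | !ver %in% c(9L, 10L))
    if (length(bad))
      stop_ubc("diagnosis: icd_version must be 9 or 10; bad row(s) %s",
               paste(utils::head(rows[bad], 5), collapse = ", "))
    data.table(patient_id = dt$patient_id,
               diag_date = parse_iso_date(dt$diag_date, "diagnosis", rows),
               icd_version = ver, icd_code = dt$icd_code,
               icdo_histology = dt$icdo_histology)
  } else if (kind == "episode") {
    bad <- which(!grepl("^[A-Z][0-9]{2,3}$", dt$opcs4_code))
    if (length(bad))
      stop_ubc("episode: invalid OPCS4 code at row(s) %s",
               paste(utils::head(rows[bad], 5), collapse = ", "))
    data.table(patient_id = dt$patient_id,
               episode_date = parse_iso_date(dt$episode_date, "episode", rows),
               opcs4_code = dt$opcs4_code)
  } else if (kind == "death") {
    dup <- which(duplicated(dt$patient_id))
    if (length(dup))
      stop_ubc("death: duplicate record for patient(s) %s (row(s) %s)",
               paste(unique(dt$patient_id[dup]), collapse = ", "),
               paste(utils::head(rows[dup], 5), collapse = ", "))
    data.table(patient_id = dt$patient_id,
               death_date = parse_iso_date(dt$death_date, "death", rows),
               primary_cause_icd = dt$primary_cause_icd)
  } else {
    yob <- suppressWarnings(as.integer(dt$year_of_birth))
    bad <- which(is.na(yob))
    if (length(bad))
      stop_ubc("sample: unparseable year_of_birth at row(s) %s",
               paste(utils::head(rows[bad], 5), collapse = ", "))
    data.table(patient_id = dt$patient_id, sex = dt$sex, year_of_birth = yob,
               white_british_flag = toupper(dt$white_british_flag) %in%
                 c("TRUE", "T", "1", "YES"))
  }
}

#' Read the SNP replication catalog
#'
#' One row per variant-outcome-subgroup combination to replicate, carrying
#' the original study's effect direction and estimate as metadata.
#'
#' @param path CSV with columns `rsid`, `allele_ref`, `allele_eff`,
#'   `outcome_label`, `subgroup`, `original_effect_direction`,
#'   `original_estimate`.
#' @return data.table of validated catalog entries.
#' @export
read_catalog <- function(path) {
  if (!file.exists(path)) stop_ubc("file not found: %s", path)
  need <- c("rsid", "allele_ref", "allele_eff", "outcome_label", "subgroup",
            "original_effect_direction", "original_estimate")
  dt <- fread(path, colClasses = "character", header = TRUE)
  if (!identical(names(dt), need))
    stop_ubc("catalog header must be exactly (%s)", paste(need, collapse = ", "))
  if (!nrow(dt)) return(dt)
  rows <- seq_len(nrow(dt)) + 1L
  bad <- which(!dt$outcome_label %in% OUTCOME_LABELS)
  if (length(bad))
    stop_ubc("catalog: unknown outcome_label '%s' at row %s",
             dt$outcome_label[bad[1]], rows[bad[1]])
  bad <- which(!dt$subgroup %in% SUBGROUPS)
  if (length(bad))
    stop_ubc("catalog: unknown subgroup '%s' at row %s (must be one of %s)",
             dt$subgroup[bad[1]], rows[bad[1]], paste(SUBGROUPS, collapse = "/"))
  bad <- which(!dt$original_effect_direction %in% c("+", "-"))
  if (length(bad))
    stop_ubc("catalog: original_effect_direction must be + or - (row %s)",
             rows[bad[1]])
  dup <- which(duplicated(dt[, .(rsid, outcome_label, subgroup)]))
  if (length(dup))
    stop_ubc("catalog: duplicate (rsid, outcome_label, subgroup) at row(s) %s",
             paste(rows[dup], collapse = ", "))
  est <- suppressWarnings(as.numeric(dt$original_estimate))
  if (any(!is.na(est) & est <= 0))
    stop_ubc("catalog: original_estimate must be positive when given")
  dt[, original_estimate := est]
  dt[]
}

#' Write a simulated cohort to plain-text files
#'
#' Emits the five record CSVs plus genotypes both as a VCF (DS and GP FORMAT
#' fields) and as a wide dosage CSV, and the ground-truth CSV (for tests).
#'
#' @param sim A `sim_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(registry = file.path(dir, "registry.csv"),
             episodes = file.path(dir, "episodes.csv"),
             deaths = file.path(dir, "deaths.csv"),
             samples = file.path(dir, "samples.csv"),
             truth = file.path(dir, "truth.csv"),
             dosages = file.path(dir, "dosages.csv"),
             vcf = file.path(dir, "genotypes.vcf"))
  fwrite(sim$registry, paths["registry"])
  fwrite(sim$episodes, paths["episodes"])
  fwrite(sim$deaths, paths["deaths"])
  fwrite(sim$samples, paths["samples"])
  fwrite(sim$truth, paths["truth"])
  dos <- data.table(patient_id = sim$samples$patient_id)
  for (v in sim$genotypes) dos[, (v$rsid) := as.numeric(v$dosage)]
  fwrite(dos, paths["dosages"])
  write_genotypes_vcf(sim$genotypes, sim$samples$patient_id, paths["vcf"])
  invisible(paths)
}

fmt_num <- function(x, digits = 6) {
  formatC(x, digits = digits, format = "g")
}

#' Write variants to a minimal VCF 4.2 with DS and GP fields
#'
#' @param genotypes Named list of `variant_data` objects.
#' @param sample_ids Patient ids in column order.
#' @param path Output `.vcf` path (uncompressed).
#' @return Invisibly, `path`.
#' @export
write_genotypes_vcf <- function(genotypes, sample_ids, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Estimated effect-allele dosage\">",
           "##FORMAT=<ID=GP,Number=G,Type=Float,Description=\"Genotype posterior probabilities\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", sample_ids), collapse = "\t"))
  body <- vapply(seq_along(genotypes), function(i) {
    v <- genotypes[[i]]
    cells <- paste0(fmt_num(v$dosage), ":",
                    fmt_num(v$prob[, 1]), ",", fmt_num(v$prob[, 2]), ",",
                    fmt_num(v$prob[, 3]))
    paste(c("1", as.character(i * 1000L), v$rsid, v$allele_ref, v$allele_eff,
            ".", "PASS", ".", "DS:GP", cells), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read genotypes from a VCF (DS preferred, GP fallback) or a dosage CSV
#'
#' For VCF input the DS FORMAT field is used when present; otherwise the
#' dosage is reconstructed from the genotype probabilities as
#' `P(het) + 2 P(hom-alt)`. Requires the VariantAnnotation package for VCF
#' input. CSV input is the wide dosage table written by [write_cohort()]
#' (alleles unknown, `prob` absent).
#'
#' @param path `.vcf` or `.csv` file.
#' @return Named list of `variant_data` objects keyed by rsID.
#' @export
read_genotypes <- function(path) {
  if (!file.exists(path)) stop_ubc("file not found: %s", path)
  if (grepl("\\.vcf$", path, ignore.case = TRUE)) {
    read_genotypes_vcf(path)
  } else {
    dt <- fread(path, header = TRUE)
    if (names(dt)[1] != "patient_id")
      stop_ubc("dosage CSV must have patient_id as its first column")
    ids <- as.character(dt$patient_id)
    out <- list()
    for (rs in names(dt)[-1]) {
      dos <- stats::setNames(as.numeric(dt[[rs]]), ids)
      out[[rs]] <- structure(
        list(rsid = rs, allele_ref = NA_character_, allele_eff = NA_character_,
             dosage = dos, prob = NULL, info = NA_real_,
             maf = {
               p <- mean(dos, na.rm = TRUE) / 2
               min(p, 1 - p)
             }),
        class = "variant_data")
    }
    out
  }
}

read_genotypes_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop_ubc("VCF input requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path)
  ids <- rownames(vcf)
  geno <- VariantAnnotation::geno(vcf)
  samples <- colnames(vcf)
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt <- vapply(as.list(VariantAnnotation::alt(vcf)), function(a)
    as.character(a)[1], character(1))
  has_ds <- "DS" %in% names(geno)
  has_gp <- "GP" %in% names(geno)
  if (!has_ds && !has_gp) stop_ubc("VCF has neither DS nor GP FORMAT fields")
  out <- list()
  for (i in seq_along(ids)) {
    prob <- NULL
    if (has_gp) {
      gp <- geno$GP
      # readVcf yields either a variants x samples matrix of length-3 lists
      # or a variants x samples x 3 array, depending on header Number
      prob <- if (is.list(gp)) do.call(rbind, gp[i, ]) else
        matrix(gp[i, , ], ncol = dim(gp)[3])
      dimnames(prob) <- NULL
    }
    dosage <- if (has_ds) as.numeric(geno$DS[i, ]) else prob[, 2] + 2 * prob[, 3]
    dosage <- stats::setNames(dosage, samples)
    tri <- if (!is.null(prob)) colSums(prob) else NULL
    out[[ids[i]]] <- structure(
      list(rsid = ids[i], allele_ref = ref[i], allele_eff = alt[i],
           dosage = dosage, prob = prob,
           info = if (!is.null(prob)) info_score(prob) else NA_real_,
           maf = if (!is.null(tri)) maf_from_counts(tri[1], tri[2], tri[3])
                 else min(mean(dosage) / 2, 1 - mean(dosage) / 2)),
      class = "variant_data")
  }
  out
}

#' @export
print.variant_data <- function(x, ...) {
  cat(sprintf("variant %s (%s>%s): n=%d, MAF=%.3f, INFO=%s\n", x$rsid,
              x$allele_ref, x$allele_eff, length(x$dosage), x$maf,
              ifelse(is.na(x$info), "NA", sprintf("%.3f", x$info))))
  invisible(x)
}
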