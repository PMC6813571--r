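Package: ubcphen
Title: Bladder Cancer Recurrence and Progression Phenotyping from
    Hospital Episode Data with Candidate-SNP Replication
Version: 0.1.0
Authors@R:
    person("UBC", "Phenotyping Contributors", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Derives urinary bladder cancer (UBC) prognostic phenotypes --
    recurrence, progression, and baseline muscle invasiveness -- from coded
    in-hospital procedure records (OPCS4) using a temporal rule engine, and
    runs candidate-SNP replication analyses over the derived outcomes:
    allele-dosage logistic and linear regression under an additive model,
    Wakefield-style approximate Bayes factors, imputation INFO scores,
    linkage-disequilibrium r-squared, and per-outcome Bonferroni correction.
    Includes a synthetic cohort generator with embedded ground truth so the
    whole pipeline is testable without access-controlled registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table (>= 1.14.0),
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation
Config/testthat/edition: 3
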