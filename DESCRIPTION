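Package: abca4cohort
Title: Variant Interpretation and Genotype-Phenotype Analysis for ABCA4 Stargardt Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for clinical cohorts with ABCA4-associated
    Stargardt disease (STGD1). Parses cDNA and protein HGVS notation and
    copy-number regions into structured variant descriptors, infers
    consequence classes, applies in-silico splice decision rules (SpliceAI
    delta-score threshold and MaxEntScan score difference) to non-canonical
    intronic variants, classifies alleles as deleterious or mild under the
    ACMG null-variant logic, assigns patients to genotype groups A/B/C,
    converts visual-acuity notations (including counting-fingers and
    hand-motion codes) to logMAR, grades phenotype severity from five
    clinical criteria, and computes cohort-level summary statistics. Ships
    an 18-patient reference cohort as plain-text fixtures and a seeded
    synthetic-cohort generator with planted genotype and severity labels for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
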