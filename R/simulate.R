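# Synthetic cohort generator.
#
# Produces patient/variant/splice-score tables with the statistical
# structure the analysis assumes, plus ground-truth labels, so the
# whole pipeline can be validated without any external data. Each
# patient is planted into a genotype group and receives alleles that
# realize that group exactly (A: two mild; B: one deleterious + one
# mild; C: two deleterious, possibly as one homozygous variant), so
# genotype-group recovery by the pipeline is deterministic. HGVS
# strings are synthesized on a toy coding model (6822-nt CDS, ten
# exons) so that parsing and gene-region tallies are exercised end to
# end. All draws come from R's RNG seeded once from `config$seed`; the
# caller's RNG state is restored on exit.

#' Simulation configuration
#'
#' Defaults encode the study conditions of an 18-patient-style STGD1
#' cohort scaled to arbitrary n: genotype-group proportions near the
#' observed 5/6/7 split, group-dependent onset distributions (group C
#' onsets in childhood, uniform 5-15 y; B uniform 6-55 y; A normal
#' mean 40 sd 12, truncated to 5-60 y), and group-level eye-logMAR
#' baselines (A 0.75, B 0.88, C 1.11) with patient- and eye-level
#' Gaussian noise, truncated to \[-0.1, 2.28\].
#'
#' @param n_patients Number of patients.
#' @param seed Integer seed; identical config + seed gives identical
#'   output.
#' @param group_proportions Named proportions over A/B/C (sum to 1).
#' @param logmar_baseline Named group-level mean logMAR.
#' @param patient_effect_sd,eye_noise_sd Gaussian noise standard
#'   deviations (logMAR).
#' @param af_probs_by_severity 3x3 matrix: rows = severity grade 1..3,
#'   columns = AF type 1..3 probabilities (also used for fundus and ERG
#'   labels).
#' @param missing_af,missing_fundus,missing_erg Per-field missingness
#'   rates.
#' @param hom_prob Probability that a group-A or group-C patient's two
#'   planted alleles are one homozygous variant.
#' @param third_allele_prob Probability of an extra mild het allele.
#' @param novelty_rate Per-variant novelty probability.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_patients = 200L, seed = 1L,
                              group_proportions = c(A = 0.28, B = 0.33, C = 0.39),
                              logmar_baseline = c(A = 0.75, B = 0.88, C = 1.11),
                              patient_effect_sd = 0.15,
                              eye_noise_sd = 0.10,
                              af_probs_by_severity = rbind(
                                c(0.70, 0.25, 0.05),
                                c(0.20, 0.60, 0.20),
                                c(0.05, 0.25, 0.70)
                              ),
                              missing_af = 0.2, missing_fundus = 0.2,
                              missing_erg = 0.2,
                              hom_prob = 0.15, third_allele_prob = 0.05,
                              novelty_rate = 0.25) {
  stopifnot(
    n_patients >= 0L,
    abs(sum(group_proportions) - 1) < 1e-8,
    all(group_proportions >= 0),
    patient_effect_sd >= 0, eye_noise_sd >= 0,
    all(dim(af_probs_by_severity) == c(3L, 3L)),
    all(abs(rowSums(af_probs_by_severity) - 1) < 1e-8),
    missing_af >= 0, missing_af <= 1,
    missing_fundus >= 0, missing_fundus <= 1,
    missing_erg >= 0, missing_erg <= 1,
    hom_prob >= 0, hom_prob <= 1,
    third_allele_prob >= 0, third_allele_prob <= 1,
    novelty_rate >= 0, novelty_rate <= 1
  )
  structure(as.list(environment()), class = "simulation_config")
}

# Toy coding model shared by the generator and its tests.
SIM_CDS_LENGTH <- 6822L
SIM_EXON_ENDS <- c(700L, 1400L, 2100L, 2800L, 3500L, 4200L, 4900L, 5600L,
                   6300L, 6822L)

sim_nt_pair <- function() sample(c("A", "C", "G", "T"), 2L)

sim_res_pair <- function() sample(setdiff(AA3, "Ter"), 2L)

# Synthesize one allele of a planted category; returns a one-row tibble
# for the variant table and (optionally) a splice-score row.
sim_allele <- function(category, novelty_rate) {
  splice_row <- NULL
  if (category == "deleterious") {
    kind <- sample(c("nonsense", "frameshift", "canonical_splice",
                     "near_splice_loss"),
                   1L, prob = c(0.35, 0.30, 0.20, 0.15))
  } else {
    kind <- sample(c("missense", "deep_intronic_quiet"), 1L,
                   prob = c(0.9, 0.1))
  }
  pos <- sample(4:(SIM_CDS_LENGTH - 3L), 1L)
  res <- (pos - 1L) %/% 3L + 1L
  nt <- sim_nt_pair()
  aa <- sim_res_pair()
  if (kind == "missense") {
    cdna <- sprintf("c.%d%s>%s", pos, nt[1], nt[2])
    prot <- sprintf("p.%s%d%s", aa[1], res, aa[2])
  } else if (kind == "nonsense") {
    cdna <- sprintf("c.%d%s>%s", pos, nt[1], nt[2])
    prot <- sprintf("p.%s%dTer", aa[1], res)
  } else if (kind == "frameshift") {
    cdna <- sprintf("c.%ddel", pos)
    prot <- sprintf("p.%s%d%sfsTer%d", aa[1], res, aa[2], sample(2:60, 1L))
  } else if (kind == "canonical_splice") {
    anchor <- sample(SIM_EXON_ENDS[-length(SIM_EXON_ENDS)], 1L)
    cdna <- sprintf("c.%d+%d%s>%s", anchor, sample(1:2, 1L), nt[1], nt[2])
    prot <- ""
  } else if (kind == "near_splice_loss") {
    anchor <- sample(SIM_EXON_ENDS[-length(SIM_EXON_ENDS)], 1L)
    off <- sample(3:8, 1L)
    cdna <- sprintf("c.%d+%d%s>%s", anchor, off, nt[1], nt[2])
    prot <- ""
    splice_row <- tibble::tibble(
      cdna_hgvs = cdna, ag = 0, al = 0, dg = 0,
      dl = round(stats::runif(1, 0.25, 0.95), 2),
      ag_pos = NA_real_, al_pos = NA_real_, dg_pos = NA_real_,
      dl_pos = off,
      maxent_ref = round(stats::runif(1, 6, 11), 3),
      maxent_var = NA_real_, maxent_delta = NA_real_, prior_severe = 0L
    )
    splice_row$maxent_var <- round(splice_row$maxent_ref -
                                     stats::runif(1, 1, 6), 3)
  } else { # deep_intronic_quiet
    anchor <- sample(SIM_EXON_ENDS[-length(SIM_EXON_ENDS)], 1L)
    off <- sample(100:900, 1L)
    cdna <- sprintf("c.%d+%d%s>%s", anchor, off, nt[1], nt[2])
    prot <- ""
    splice_row <- tibble::tibble(
      cdna_hgvs = cdna,
      ag = round(stats::runif(1, 0, 0.05), 2),
      al = round(stats::runif(1, 0, 0.05), 2),
      dg = round(stats::runif(1, 0, 0.05), 2),
      dl = round(stats::runif(1, 0, 0.05), 2),
      ag_pos = NA_real_, al_pos = NA_real_, dg_pos = NA_real_,
      dl_pos = NA_real_, maxent_ref = NA_real_, maxent_var = NA_real_,
      maxent_delta = NA_real_, prior_severe = 0L
    )
  }
  list(
    variant = tibble::tibble(
      cdna_hgvs = cdna, protein_hgvs = prot, genomic_region = "",
      novel = stats::rbinom(1, 1, novelty_rate)
    ),
    splice = splice_row
  )
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
}

#' Simulate a synthetic cohort
#'
#' @param config A [simulation_config()].
#' @return A list of tibbles in the on-disk table schemas: `patients`,
#'   `variants`, `splice`, plus `truth` (`patient_id`, `group`,
#'   `severity_grade`, and `fields_complete` marking records where all
#'   five severity criteria fields were generated non-missing).
#' @examples
#' sim <- simulate_cohort(simulation_config(n_patients = 5, seed = 7))
#' sim$truth
#' @export
simulate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(config$seed)

  n <- config$n_patients
  empty_patients <- tibble::tibble(
    patient_id = character(), sex = character(), onset_age = character(),
    exam_age = character(), acuity_od = character(), acuity_os = character(),
    fundus_type = character(), af_type = character(), erg_type = character(),
    evaluable = character(), reported_group = character(),
    reported_severity = character()
  )
  empty_variants <- tibble::tibble(
    patient_id = character(), cdna_hgvs = character(),
    protein_hgvs = character(), genomic_region = character(),
    zygosity = character(), novel = character()
  )
  empty_splice <- tibble::tibble(
    cdna_hgvs = character(), ag = numeric(), al = numeric(), dg = numeric(),
    dl = numeric(), ag_pos = numeric(), al_pos = numeric(),
    dg_pos = numeric(), dl_pos = numeric(), maxent_ref = numeric(),
    maxent_var = numeric(), maxent_delta = numeric(), prior_severe = integer()
  )
  if (n == 0L) {
    return(list(patients = empty_patients, variants = empty_variants,
                splice = empty_splice,
                truth = tibble::tibble(patient_id = character(),
                                       group = character(),
                                       severity_grade = integer())))
  }

  groups <- sample(names(config$group_proportions), n, replace = TRUE,
                   prob = config$group_proportions)
  ids <- sprintf("S%03d", seq_len(n))

  patients <- vector("list", n)
  variants <- vector("list", n)
  splice <- list()
  truth <- vector("list", n)

  for (i in seq_len(n)) {
    g <- groups[[i]]
    onset <- switch(g,
      A = round(rtrunc_norm(1, 40, 12, 5, 60), 0),
      B = round(stats::runif(1, 6, 55), 0),
      C = round(stats::runif(1, 5, 15), 0)
    )
    exam <- onset + round(stats::runif(1, 0, 15), 0)
    mu <- config$logmar_baseline[[g]] + stats::rnorm(1, 0, config$patient_effect_sd)
    eyes <- pmin(pmax(mu + stats::rnorm(2, 0, config$eye_noise_sd), -0.1), 2.28)
    eyes <- round(eyes, 2)
    # a patient eye pinned to the truncation ceiling has no letter score:
    # record it as the hand-motion code
    acuity <- ifelse(eyes >= 2.28, "HM", format(eyes, trim = TRUE))
    better <- min(eyes)

    # latent severity from onset + acuity decides label probabilities
    latent <- suppressWarnings(classify_severity(onset, better))
    p_lab <- config$af_probs_by_severity[latent$grade, ]
    draw_label <- function(missing_rate) {
      if (stats::runif(1) < missing_rate) NA_integer_
      else sample(1:3, 1L, prob = p_lab)
    }
    fundus <- draw_label(config$missing_fundus)
    af <- draw_label(config$missing_af)
    erg <- draw_label(config$missing_erg)
    truth_sev <- suppressWarnings(
      classify_severity(onset, better, fundus, af, erg)
    )

    # allele plan realizing the planted group
    plan <- switch(g,
      A = list(categories = c("non_deleterious", "non_deleterious"),
               zygosity = c("het", "het")),
      B = list(categories = c("deleterious", "non_deleterious"),
               zygosity = c("het", "het")),
      C = list(categories = c("deleterious", "deleterious"),
               zygosity = c("het", "het"))
    )
    if (g %in% c("A", "C") && stats::runif(1) < config$hom_prob) {
      plan <- list(categories = plan$categories[1L], zygosity = "hom")
    }
    if (stats::runif(1) < config$third_allele_prob) {
      plan$categories <- c(plan$categories, "non_deleterious")
      plan$zygosity <- c(plan$zygosity, "het")
    }

    pv <- list()
    seen <- character(0)
    for (k in seq_along(plan$categories)) {
      repeat {
        al <- sim_allele(plan$categories[[k]], config$novelty_rate)
        if (!al$variant$cdna_hgvs %in% seen) break
      }
      seen <- c(seen, al$variant$cdna_hgvs)
      pv[[k]] <- al$variant |>
        dplyr::mutate(patient_id = ids[[i]], zygosity = plan$zygosity[[k]],
                      .before = 1L)
      if (!is.null(al$splice)) splice[[length(splice) + 1L]] <- al$splice
    }

    patients[[i]] <- tibble::tibble(
      patient_id = ids[[i]],
      sex = sample(c("M", "F"), 1L),
      onset_age = format(onset, trim = TRUE),
      exam_age = format(exam, trim = TRUE),
      acuity_od = acuity[[1]], acuity_os = acuity[[2]],
      fundus_type = ifelse(is.na(fundus), "", as.character(fundus)),
      af_type = ifelse(is.na(af), "", as.character(af)),
      erg_type = ifelse(is.na(erg), "", as.character(erg)),
      evaluable = "1", reported_group = "", reported_severity = ""
    )
    variants[[i]] <- dplyr::bind_rows(pv)
    truth[[i]] <- tibble::tibble(
      patient_id = ids[[i]], group = g,
      severity_grade = truth_sev$grade,
      fields_complete = truth_sev$fields_available == 5L
    )
  }

  variants_tbl <- dplyr::bind_rows(variants) |>
    dplyr::mutate(novel = as.character(.data$novel)) |>
    dplyr::relocate("patient_id", "cdna_hgvs", "protein_hgvs",
                    "genomic_region", "zygosity", "novel")
  splice_tbl <- if (length(splice) > 0L) {
    dplyr::bind_rows(splice) |> dplyr::distinct(.data$cdna_hgvs, .keep_all = TRUE)
  } else {
    empty_splice
  }
  list(
    patients = dplyr::bind_rows(patients),
    variants = variants_tbl,
    splice = splice_tbl,
    truth = dplyr::bind_rows(truth)
  )
}
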