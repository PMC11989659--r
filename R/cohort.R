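# Cohort-level summary statistics.
#
# Reproduces, from tabulated per-patient data, the descriptive numbers a
# cohort report prints: onset-strata means (adult vs childhood/
# adolescent onset, split at 18 years), the late-onset tally (onset >=
# 45 years), per-eye mean logMAR, the autofluorescence-type
# distribution, zygosity breakdown, genotype-group counts and per-group
# statistics, the genotype x severity cross-tabulation over evaluable
# patients, the distinct-variant consequence spectrum, and novelty
# counts.
#
# Group-level central values are arithmetic means; a true median column
# is reported besides. Full-precision values are retained; rounding is
# applied only in report output.

#' Summarize a cohort
#'
#' @param patients Tibble of patient records as returned by
#'   [read_patient_table()] (needs `patient_id`, `sex`, `onset_age`,
#'   `logmar_od`, `logmar_os`, `af_type`, `evaluable`).
#' @param variants Tibble of annotated variants as returned by
#'   [annotate_variants()] (needs `patient_id`, `key`, `consequence`,
#'   `novel`, `zygosity`).
#' @param assignments Tibble of genotype assignments as returned by
#'   [assign_genotype_groups()] (needs `patient_id`, `group`).
#' @param severities Tibble with `patient_id` and `grade` (1/2/3 or
#'   `NA`); only evaluable patients enter severity-dependent fields.
#' @param adult_onset_threshold Years; onset at or above this is the
#'   adult stratum (default 18).
#' @param late_onset_threshold Years; onset at or above this is
#'   late-onset disease (default 45).
#' @return An object of class `cohort_summary` (a list; see the methods
#'   vignette for the field-by-field description).
#' @export
summarize_cohort <- function(patients, variants, assignments, severities,
                             adult_onset_threshold = 18,
                             late_onset_threshold = 45) {
  if (nrow(patients) == 0L) {
    rlang::abort("empty cohort", class = "abca4_validation_error")
  }

  adult <- patients$onset_age >= adult_onset_threshold
  mean_or_na <- function(x) if (length(x) == 0L) NA_real_ else mean(x)

  eyes <- c(patients$logmar_od, patients$logmar_os)

  af <- patients$af_type[!is.na(patients$af_type)]
  af_counts <- vapply(1:3, function(k) sum(af == k), integer(1))
  names(af_counts) <- paste0("type", 1:3)

  zyg <- patients |>
    dplyr::inner_join(
      variants |>
        dplyr::group_by(.data$patient_id) |>
        dplyr::summarise(
          n_variants = dplyr::n(),
          n_alleles = sum(ifelse(.data$zygosity == "hom", 2L, 1L)),
          any_hom = any(.data$zygosity == "hom"),
          .groups = "drop"
        ),
      by = "patient_id"
    ) |>
    dplyr::mutate(zyg_class = dplyr::case_when(
      .data$n_alleles >= 3L ~ "triallelic",
      .data$any_hom ~ "homozygous",
      .data$n_alleles == 2L ~ "biallelic_het",
      TRUE ~ "monoallelic"
    ))
  zygosity_counts <- c(
    biallelic_het = sum(zyg$zyg_class == "biallelic_het"),
    homozygous = sum(zyg$zyg_class == "homozygous"),
    triallelic = sum(zyg$zyg_class == "triallelic"),
    monoallelic = sum(zyg$zyg_class == "monoallelic")
  )

  asg <- assignments[assignments$group %in% c("A", "B", "C"), ]
  group_counts <- vapply(c("A", "B", "C"),
                         function(g) sum(asg$group == g), integer(1))

  pg <- patients |>
    dplyr::inner_join(asg[, c("patient_id", "group")], by = "patient_id")
  group_stats <- pg |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      onset_mean = mean(.data$onset_age),
      onset_median = stats::median(.data$onset_age),
      onset_min = min(.data$onset_age),
      onset_max = max(.data$onset_age),
      bcva_mean_all_eyes = mean(c(.data$logmar_od, .data$logmar_os)),
      bcva_median_all_eyes = stats::median(c(.data$logmar_od, .data$logmar_os)),
      n_eyes = 2L * dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$group)

  sev <- patients |>
    dplyr::filter(.data$evaluable) |>
    dplyr::inner_join(severities, by = "patient_id") |>
    dplyr::filter(!is.na(.data$grade))
  severity_counts <- vapply(1:3, function(k) sum(sev$grade == k), integer(1))
  names(severity_counts) <- c("mild", "moderate", "severe")
  n_evaluable <- nrow(sev)

  crosstab <- sev |>
    dplyr::inner_join(asg[, c("patient_id", "group")], by = "patient_id") |>
    dplyr::count(.data$group, .data$grade) |>
    tidyr::complete(
      group = c("A", "B", "C"), grade = 1:3, fill = list(n = 0L)
    ) |>
    tidyr::pivot_wider(names_from = "grade", values_from = "n",
                       names_prefix = "severity_")

  spec <- variant_spectrum(variants)

  structure(
    list(
      n_patients = nrow(patients),
      n_adult = sum(adult), n_child = sum(!adult),
      onset_mean_adult = mean_or_na(patients$onset_age[adult]),
      onset_mean_child = mean_or_na(patients$onset_age[!adult]),
      n_late_onset = sum(patients$onset_age >= late_onset_threshold),
      mean_logmar_od = mean(patients$logmar_od),
      mean_logmar_os = mean(patients$logmar_os),
      logmar_range = range(eyes),
      af_counts = af_counts, n_af_available = length(af),
      zygosity_counts = zygosity_counts,
      group_counts = group_counts,
      group_percent = 100 * group_counts / sum(group_counts),
      group_stats = group_stats,
      severity_counts = severity_counts,
      severity_percent = 100 * severity_counts / max(n_evaluable, 1L),
      n_evaluable = n_evaluable,
      n_unclassifiable = nrow(patients) - n_evaluable,
      crosstab = crosstab,
      spectrum = spec$spectrum,
      n_distinct_variants = spec$n_distinct,
      n_novel = spec$n_novel
    ),
    class = "cohort_summary"
  )
}

#' Distinct-variant consequence spectrum
#'
#' Deduplicates variants by their normalized cDNA string (genomic string
#' for CNVs) and counts distinct variants per consequence class, plus
#' the number of distinct novel variants.
#'
#' @param variants Annotated variant tibble (`key`, `consequence`,
#'   `novel`).
#' @return A list: `spectrum` (named integer vector over all consequence
#'   classes), `n_distinct`, `n_novel`.
#' @export
variant_spectrum <- function(variants) {
  spectrum <- stats::setNames(integer(length(CONSEQUENCE_LEVELS)),
                              CONSEQUENCE_LEVELS)
  if (nrow(variants) == 0L) {
    return(list(spectrum = spectrum, n_distinct = 0L, n_novel = 0L))
  }
  distinct <- variants |>
    dplyr::distinct(.data$key, .keep_all = TRUE)
  tab <- table(distinct$consequence)
  spectrum[names(tab)] <- as.integer(tab)
  list(
    spectrum = spectrum,
    n_distinct = nrow(distinct),
    n_novel = sum(as.integer(distinct$novel) == 1L)
  )
}

#' Count patients (or alleles) carrying a variant
#'
#' @param variants Annotated variant tibble (`patient_id`, `key`,
#'   `zygosity`).
#' @param target A cDNA HGVS string (normalized before matching).
#' @param mode `"patients"` counts carriers (a homozygote counts once);
#'   `"alleles"` counts allele copies (a homozygote counts twice).
#' @return An integer count.
#' @examples
#' \dontrun{occurrence_count(variants, "c.2894A>G")}
#' @export
occurrence_count <- function(variants, target, mode = c("patients", "alleles")) {
  mode <- match.arg(mode)
  key <- normalize_hgvs(target)
  hits <- variants[variants$key == key, ]
  if (nrow(hits) == 0L) return(0L)
  if (mode == "patients") {
    length(unique(hits$patient_id))
  } else {
    sum(ifelse(hits$zygosity == "hom", 2L, 1L))
  }
}

#' Read a transcript/domain gene model
#'
#' The model is a JSON file with a `transcript` label, an ordered exon
#' list (`index`, `cdna_start`, `cdna_end`; 1-based inclusive,
#' contiguous, non-overlapping) and a protein-domain map (`name`,
#' `aa_start`, `aa_end`; non-overlapping).
#'
#' @param path Path to the JSON file.
#' @return An object of class `gene_model`.
#' @export
read_gene_model <- function(path) {
  raw <- jsonlite::fromJSON(path)
  exons <- tibble::as_tibble(raw$exons) |> dplyr::arrange(.data$index)
  domains <- tibble::as_tibble(raw$domains)
  if (any(exons$cdna_start > exons$cdna_end)) {
    rlang::abort("exon with start > end", class = "abca4_validation_error")
  }
  if (nrow(exons) > 1L &&
      any(exons$cdna_start[-1L] != exons$cdna_end[-nrow(exons)] + 1L)) {
    rlang::abort("exon cDNA intervals must be contiguous",
                 class = "abca4_validation_error")
  }
  if (nrow(domains) > 1L) {
    d <- domains[order(domains$aa_start), ]
    if (any(d$aa_start[-1L] <= d$aa_end[-nrow(d)])) {
      rlang::abort("domain ranges must not overlap",
                   class = "abca4_validation_error")
    }
  }
  structure(
    list(transcript = raw$transcript, exons = exons, domains = domains),
    class = "gene_model"
  )
}

# Locate the exon index containing a cDNA position, NA if outside.
locate_exon <- function(model, pos) {
  hit <- which(model$exons$cdna_start <= pos & pos <= model$exons$cdna_end)
  if (length(hit) == 1L) model$exons$index[hit] else NA_integer_
}

#' Tally variants per exon, intron, and protein domain
#'
#' Exonic variants are located by their anchor cDNA position; intronic
#' variants by the flanking exon pair (a positive offset falls in the
#' intron after the anchor exon, a negative offset in the intron before
#' it); protein domains by residue number when a protein annotation is
#' present. Every locatable variant contributes to exactly one
#' exon-or-intron bin; variants whose anchor lies beyond the model span
#' are reported as unlocatable with a warning.
#'
#' @param descriptors List of `variant_descriptor` objects (distinct
#'   variants).
#' @param model A `gene_model`.
#' @return A list of tibbles: `exons` (`exon`, `n`), `introns`
#'   (`intron`, `n`), `domains` (`domain`, `n`), and `unlocatable`
#'   (`key`).
#' @export
region_tally <- function(descriptors, model) {
  stopifnot(inherits(model, "gene_model"))
  n_exons <- nrow(model$exons)
  exon_n <- stats::setNames(integer(n_exons), model$exons$index)
  intron_n <- stats::setNames(integer(max(n_exons - 1L, 0L)),
                              seq_len(max(n_exons - 1L, 0L)))
  domain_n <- stats::setNames(integer(nrow(model$domains)),
                              model$domains$name)
  unlocatable <- character(0)

  for (v in descriptors) {
    placed <- FALSE
    if (!is.null(v$cdna)) {
      ex <- locate_exon(model, v$cdna$anchor_position)
      if (is.na(ex)) {
        unlocatable <- c(unlocatable, v$key)
      } else if (v$cdna$intron_offset == 0L) {
        exon_n[as.character(ex)] <- exon_n[as.character(ex)] + 1L
        placed <- TRUE
      } else {
        intr <- if (v$cdna$intron_offset > 0L) ex else ex - 1L
        if (intr >= 1L && intr <= n_exons - 1L) {
          intron_n[as.character(intr)] <- intron_n[as.character(intr)] + 1L
          placed <- TRUE
        } else {
          unlocatable <- c(unlocatable, v$key)
        }
      }
    } else {
      unlocatable <- c(unlocatable, v$key)
    }
    if (placed && !is.null(v$protein)) {
      d <- which(model$domains$aa_start <= v$protein$residue_number &
                   v$protein$residue_number <= model$domains$aa_end)
      if (length(d) == 1L) {
        domain_n[d] <- domain_n[d] + 1L
      }
    }
  }
  if (length(unlocatable) > 0L) {
    rlang::warn(paste0(length(unlocatable),
                       " variant(s) could not be located on the gene model"))
  }
  list(
    exons = tibble::tibble(exon = model$exons$index, n = unname(exon_n)),
    introns = tibble::tibble(intron = as.integer(names(intron_n)),
                             n = unname(intron_n)),
    domains = tibble::tibble(domain = model$domains$name,
                             n = unname(domain_n)),
    unlocatable = tibble::tibble(key = unlocatable)
  )
}

#' Report known print-versus-recompute discrepancies
#'
#' A small validation report for the packaged 18-patient reference
#' cohort: quantities whose published rounded value does not match what
#' the tabulated per-patient data recompute to. These are surfaced, not
#' forced.
#'
#' @param summary A `cohort_summary` computed from the reference cohort.
#' @return A tibble with `quantity`, `recomputed`, `published`,
#'   `consistent`.
#' @export
reference_discrepancy_report <- function(summary) {
  stopifnot(inherits(summary, "cohort_summary"))
  ga <- summary$group_stats$bcva_mean_all_eyes[summary$group_stats$group == "A"]
  tibble::tibble(
    quantity = c(
      "mean logMAR, left eye",
      "group A mean BCVA (all eyes)",
      "distinct variant total",
      "minimum logMAR across eyes"
    ),
    recomputed = c(
      round(summary$mean_logmar_os, 2),
      round(if (length(ga) == 1L) ga else NA_real_, 3),
      as.numeric(summary$n_distinct_variants),
      summary$logmar_range[[1L]]
    ),
    published = c(0.91, 0.748, 31, -0.10),
    consistent = recomputed == published
  )
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary> ", x$n_patients, " patients\n", sep = "")
  cat("  onset: adult mean ", round(x$onset_mean_adult, 1), " (n=", x$n_adult,
      "), child mean ", round(x$onset_mean_child, 1), " (n=", x$n_child,
      "), late-onset n=", x$n_late_onset, "\n", sep = "")
  cat("  mean logMAR OD ", round(x$mean_logmar_od, 2), ", OS ",
      round(x$mean_logmar_os, 2), "\n", sep = "")
  cat("  groups A/B/C: ", paste(x$group_counts, collapse = "/"),
      "; severity mild/moderate/severe: ",
      paste(x$severity_counts, collapse = "/"),
      " of ", x$n_evaluable, " evaluable\n", sep = "")
  cat("  distinct variants ", x$n_distinct_variants, " (novel ", x$n_novel,
      ")\n", sep = "")
  invisible(x)
}
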