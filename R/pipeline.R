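# Pipeline composition: variants -> consequences -> splice calls ->
# allele severities -> genotype groups -> severity classes -> cohort
# summary. Output is deterministic: identical inputs and configuration
# produce byte-identical JSON.

#' Annotate a variant table
#'
#' Parses each row's HGVS/genomic notation, infers the consequence
#' class, attaches the splice-score row (matched by normalized cDNA
#' string) and its [call_splice_effect()] result for non-canonical
#' intronic variants, and classifies each allele as deleterious or
#' mild.
#'
#' @param variants Tibble from [read_variant_table()].
#' @param splice Tibble from [read_splice_table()], or `NULL` when no
#'   scores are available.
#' @param config A [pipeline_config()].
#' @return The variant tibble with added columns `key`, `consequence`,
#'   `splice_effect`, `delta_max`, `severity_category`,
#'   `severity_basis`, and a `descriptors` attribute holding the parsed
#'   `variant_descriptor` objects.
#' @export
annotate_variants <- function(variants, splice = NULL,
                              config = pipeline_config()) {
  n <- nrow(variants)
  descriptors <- vector("list", n)
  key <- consequence <- effect <- basis <- category <- character(n)
  delta_max <- rep(NA_real_, n)
  effect[] <- NA_character_

  for (i in seq_len(n)) {
    r <- variants[i, ]
    d <- variant_descriptor(
      cdna_hgvs = r$cdna_hgvs, protein_hgvs = r$protein_hgvs,
      genomic_region = r$genomic_region, novel = r$novel == 1L,
      near_splice_window = config$near_splice_window
    )
    descriptors[[i]] <- d
    key[i] <- d$key
    consequence[i] <- d$consequence

    splice_effect <- NULL
    prior_severe <- FALSE
    if (d$consequence %in% c("near_splice_intronic", "deep_intronic") &&
        !is.null(splice)) {
      hit <- which(splice$cdna_hgvs == d$key)
      if (length(hit) >= 1L) {
        row <- splice[hit[[1L]], ]
        pred <- splice_prediction_from_row(row)
        call <- call_splice_effect(
          pred,
          delta_threshold = config$delta_threshold,
          in_functional_site = d$consequence == "near_splice_intronic"
        )
        splice_effect <- call
        effect[i] <- call$effect
        delta_max[i] <- call$delta_max
        prior_severe <- identical(pred$prior_severe_phenotype, TRUE)
      }
    }
    sev <- assign_allele_severity(d$consequence, splice_effect, prior_severe)
    category[i] <- sev$category
    basis[i] <- sev$basis
  }

  out <- variants |>
    dplyr::mutate(
      key = key, consequence = consequence, splice_effect = effect,
      delta_max = delta_max, severity_category = category,
      severity_basis = basis
    )
  attr(out, "descriptors") <- descriptors
  out
}

#' Assign genotype groups for every patient
#'
#' @param annotated Output of [annotate_variants()].
#' @return A tibble `patient_id`, `group`, `n_deleterious`, `n_mild`,
#'   `total_alleles`. Patients with fewer than two detected alleles are
#'   `unassigned` (with a warning) and excluded from group statistics
#'   downstream.
#' @export
assign_genotype_groups <- function(annotated) {
  out <- annotated |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::group_modify(function(g, key) {
      a <- assign_genotype_group(g$severity_category, g$zygosity)
      tibble::tibble(
        group = a$group, n_deleterious = a$n_deleterious_alleles,
        n_mild = a$n_mild_alleles, total_alleles = a$total_alleles
      )
    }) |>
    dplyr::ungroup()
  un <- out$patient_id[out$group == "unassigned"]
  if (length(un) > 0L) {
    rlang::warn(paste0("patient(s) with a single detected allele left unassigned: ",
                       paste(un, collapse = ", ")))
  }
  out
}

#' Derive per-patient severity classes
#'
#' @param patients Tibble from [read_patient_table()].
#' @param config A [pipeline_config()]; `severity_source` decides
#'   whether the tabulated severity labels or the five-criteria
#'   classifier supply the class.
#' @return A tibble `patient_id`, `grade`, `klass`, `mild_hits`,
#'   `severe_hits`.
#' @export
compute_severities <- function(patients, config = pipeline_config()) {
  if (config$severity_source == "table_labels") {
    return(tibble::tibble(
      patient_id = patients$patient_id,
      grade = patients$reported_severity,
      klass = c("mild", "moderate", "severe")[patients$reported_severity],
      mild_hits = NA_integer_, severe_hits = NA_integer_
    ))
  }
  purrr::pmap_dfr(
    patients[, c("patient_id", "onset_age", "better_eye_logmar",
                 "fundus_type", "af_type", "erg_type")],
    function(patient_id, onset_age, better_eye_logmar, fundus_type,
             af_type, erg_type) {
      s <- classify_severity(onset_age, better_eye_logmar, fundus_type,
                             af_type, erg_type)
      tibble::tibble(
        patient_id = patient_id, grade = s$grade, klass = s$klass,
        mild_hits = s$mild_hits, severe_hits = s$severe_hits
      )
    }
  )
}

#' Run the full pipeline
#'
#' @param patients,variants,splice Input tibbles (see the readers);
#'   `splice` may be `NULL`.
#' @param config A [pipeline_config()].
#' @return An object of class `pipeline_result`: `summary` (a
#'   [summarize_cohort()] result), `annotated` variants, `assignments`,
#'   `severities`, and an `audit` tibble listing every allele's
#'   classification basis.
#' @export
run_pipeline <- function(patients, variants, splice = NULL,
                         config = pipeline_config()) {
  if (nrow(patients) == 0L) {
    rlang::abort("empty patient table", class = "abca4_validation_error")
  }
  orphans <- setdiff(unique(variants$patient_id), patients$patient_id)
  if (length(orphans) > 0L) {
    rlang::abort(
      paste0("variant rows cite unknown patient id(s): ",
             paste(orphans, collapse = ", ")),
      class = "abca4_io_error"
    )
  }

  annotated <- annotate_variants(variants, splice, config)
  assignments <- assign_genotype_groups(annotated)
  severities <- compute_severities(patients, config)
  summary <- summarize_cohort(
    patients, annotated, assignments, severities,
    adult_onset_threshold = config$adult_onset_threshold,
    late_onset_threshold = config$late_onset_threshold
  )
  audit <- annotated[, c("patient_id", "key", "consequence", "zygosity",
                         "splice_effect", "severity_category",
                         "severity_basis")]
  structure(
    list(summary = summary, annotated = annotated,
         assignments = assignments, severities = severities,
         audit = audit, config = config),
    class = "pipeline_result"
  )
}

#' Serialize a pipeline result as canonical JSON
#'
#' Fixed key order, fixed float formatting, no environment-dependent
#' fields: repeated runs on identical inputs give byte-identical text.
#'
#' @param result A `pipeline_result`.
#' @return A JSON string.
#' @export
pipeline_json <- function(result) {
  stopifnot(inherits(result, "pipeline_result"))
  s <- result$summary
  payload <- list(
    summary = list(
      n_patients = s$n_patients,
      n_adult = s$n_adult, n_child = s$n_child,
      onset_mean_adult = s$onset_mean_adult,
      onset_mean_child = s$onset_mean_child,
      n_late_onset = s$n_late_onset,
      mean_logmar_od = s$mean_logmar_od,
      mean_logmar_os = s$mean_logmar_os,
      af_counts = as.list(s$af_counts),
      n_af_available = s$n_af_available,
      zygosity_counts = as.list(s$zygosity_counts),
      group_counts = as.list(s$group_counts),
      group_stats = s$group_stats,
      severity_counts = as.list(s$severity_counts),
      n_evaluable = s$n_evaluable,
      crosstab = s$crosstab,
      spectrum = as.list(s$spectrum),
      n_distinct_variants = s$n_distinct_variants,
      n_novel = s$n_novel
    ),
    assignments = result$assignments,
    severities = result$severities,
    audit = result$audit
  )
  jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, na = "null",
                   pretty = TRUE)
}

#' @export
print.pipeline_result <- function(x, ...) {
  print(x$summary)
  invisible(x)
}
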