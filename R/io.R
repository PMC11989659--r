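# Table readers/writers and pipeline configuration.
#
# All tables are tab-delimited UTF-8 with "." as the decimal separator;
# an empty string marks an absent field. TSV is preferred over CSV so
# that commas in free-text notes never corrupt a row. En/em dashes are
# normalized to the ASCII hyphen before HGVS parsing.

required_columns <- function(df, cols, what, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    rlang::abort(
      paste0(what, " ", path, " is missing required column(s): ",
             paste(missing, collapse = ", ")),
      class = "abca4_io_error"
    )
  }
}

read_tsv_chr <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                  na = character(), progress = FALSE,
                  show_col_types = FALSE)
}

int_or_na <- function(x) {
  x <- trimws(x)
  ifelse(nzchar(x), suppressWarnings(as.integer(x)), NA_integer_)
}

num_or_na <- function(x) {
  x <- trimws(x)
  ifelse(nzchar(x), suppressWarnings(as.numeric(x)), NA_real_)
}

#' Pipeline configuration
#'
#' Collects every tunable threshold of the pipeline in one place.
#'
#' @param delta_threshold SpliceAI delta-score call threshold (default
#'   0.2).
#' @param near_splice_window Intronic offset (nt) separating near-splice
#'   from deep intronic variants (default 20).
#' @param adult_onset_threshold Years (default 18).
#' @param late_onset_threshold Years (default 45).
#' @param low_vision_codes Named logMAR values for counting fingers and
#'   hand motion.
#' @param severity_source `"table_labels"` uses the severity labels of
#'   the patient table (appropriate when fundus/ERG types were graded
#'   clinically but not tabulated per patient); `"computed"` derives
#'   severity from the five-criteria classifier on the tabulated fields.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(delta_threshold = 0.2,
                            near_splice_window = 20L,
                            adult_onset_threshold = 18,
                            late_onset_threshold = 45,
                            low_vision_codes = c(CF = 1.98, HM = 2.28),
                            severity_source = c("table_labels", "computed")) {
  stopifnot(delta_threshold > 0, delta_threshold < 1,
            near_splice_window >= 3,
            adult_onset_threshold > 0, late_onset_threshold > 0,
            all(low_vision_codes >= 0), all(low_vision_codes <= 2.28))
  structure(
    list(
      delta_threshold = delta_threshold,
      near_splice_window = as.integer(near_splice_window),
      adult_onset_threshold = adult_onset_threshold,
      late_onset_threshold = late_onset_threshold,
      low_vision_codes = low_vision_codes,
      severity_source = match.arg(severity_source)
    ),
    class = "pipeline_config"
  )
}

#' Read a patient table
#'
#' Validates every row; rows violating a record invariant (unknown sex,
#' exam age before onset, bad type label, unparseable acuity) are
#' rejected with a line-numbered message collected in the
#' `"row_errors"` attribute (and a warning); a missing required column
#' is a hard error.
#'
#' @param path Path to the TSV.
#' @param config A [pipeline_config()].
#' @return A tibble with one validated row per patient; acuities are
#'   returned both raw (`acuity_od`/`acuity_os`) and converted
#'   (`logmar_od`/`logmar_os`), plus `better_eye_logmar`.
#' @export
read_patient_table <- function(path, config = pipeline_config()) {
  df <- read_tsv_chr(path)
  required_columns(df, c("patient_id", "sex", "onset_age", "exam_age",
                         "acuity_od", "acuity_os", "af_type", "evaluable"),
                   "patient table", path)
  for (opt in c("fundus_type", "erg_type", "reported_group",
                "reported_severity")) {
    if (!opt %in% names(df)) df[[opt]] <- ""
  }
  if (nrow(df) == 0L) {
    out <- tibble::tibble(
      patient_id = character(), sex = character(), onset_age = numeric(),
      exam_age = numeric(), acuity_od = character(), acuity_os = character(),
      logmar_od = numeric(), logmar_os = numeric(),
      better_eye_logmar = numeric(), fundus_type = integer(),
      af_type = integer(), erg_type = integer(), evaluable = logical(),
      reported_group = character(), reported_severity = integer()
    )
    attr(out, "row_errors") <- character(0)
    return(out)
  }

  errors <- character(0)
  keep <- logical(nrow(df))
  rows <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    line <- i + 1L  # header is line 1
    err <- function(msg) {
      errors <<- c(errors, paste0("line ", line, ": ", msg))
    }
    onset <- num_or_na(r$onset_age)
    exam <- num_or_na(r$exam_age)
    if (!r$sex %in% c("M", "F")) { err("sex must be M or F"); next }
    if (is.na(onset) || onset < 0) { err("invalid onset_age"); next }
    if (is.na(exam) || exam < onset) {
      err("exam_age must be >= onset_age"); next
    }
    lv <- config$low_vision_codes
    logmar <- tryCatch(
      c(to_logmar(r$acuity_od, lv), to_logmar(r$acuity_os, lv)),
      error = function(e) NULL
    )
    if (is.null(logmar)) { err("unparseable acuity"); next }
    types <- lapply(c("fundus_type", "af_type", "erg_type"), function(col) {
      int_or_na(r[[col]])
    })
    if (any(vapply(types, function(t) !is.na(t) && !t %in% 1:3, logical(1)))) {
      err("type labels must be 1, 2, or 3"); next
    }
    ev <- int_or_na(r$evaluable)
    if (is.na(ev) || !ev %in% 0:1) { err("evaluable must be 0 or 1"); next }
    keep[i] <- TRUE
    rows[[i]] <- tibble::tibble(
      patient_id = r$patient_id, sex = r$sex, onset_age = onset,
      exam_age = exam, acuity_od = r$acuity_od, acuity_os = r$acuity_os,
      logmar_od = logmar[[1]], logmar_os = logmar[[2]],
      better_eye_logmar = min(logmar),
      fundus_type = types[[1]], af_type = types[[2]], erg_type = types[[3]],
      evaluable = ev == 1L,
      reported_group = ifelse(nzchar(trimws(r$reported_group)),
                              trimws(r$reported_group), NA_character_),
      reported_severity = int_or_na(r$reported_severity)
    )
  }
  out <- dplyr::bind_rows(rows[keep])
  if (length(errors) > 0L) {
    rlang::warn(c("rejected patient rows:", errors))
  }
  if (anyDuplicated(out$patient_id)) {
    rlang::abort("duplicate patient_id in patient table",
                 class = "abca4_io_error")
  }
  attr(out, "row_errors") <- errors
  out
}

#' Read a variant table
#'
#' @param path Path to the TSV (`patient_id`, `cdna_hgvs`,
#'   `protein_hgvs`, `genomic_region`, `zygosity`, `novel`).
#' @return A tibble with trimmed, dash-normalized notation columns.
#' @export
read_variant_table <- function(path) {
  df <- read_tsv_chr(path)
  required_columns(df, c("patient_id", "cdna_hgvs", "protein_hgvs",
                         "genomic_region", "zygosity", "novel"),
                   "variant table", path)
  df <- df |>
    dplyr::mutate(
      cdna_hgvs = normalize_hgvs(.data$cdna_hgvs),
      protein_hgvs = normalize_hgvs(.data$protein_hgvs),
      genomic_region = normalize_hgvs(.data$genomic_region),
      novel = int_or_na(.data$novel)
    )
  bad_zyg <- !df$zygosity %in% c("het", "hom")
  if (any(bad_zyg)) {
    rlang::abort(paste0("invalid zygosity at line(s) ",
                        paste(which(bad_zyg) + 1L, collapse = ", ")),
                 class = "abca4_io_error")
  }
  if (any(is.na(df$novel) | !df$novel %in% 0:1)) {
    rlang::abort("novel must be 0 or 1", class = "abca4_io_error")
  }
  no_desc <- !nzchar(df$cdna_hgvs) & !nzchar(df$genomic_region)
  if (any(no_desc)) {
    rlang::abort(paste0("variant row(s) without cDNA or genomic description: line(s) ",
                        paste(which(no_desc) + 1L, collapse = ", ")),
                 class = "abca4_io_error")
  }
  df
}

#' Read a splice-score table
#'
#' @param path Path to the TSV (`cdna_hgvs`, four delta-score columns
#'   `ag`/`al`/`dg`/`dl` with positions, `maxent_ref`, `maxent_var`,
#'   optional `maxent_delta`, `prior_severe`).
#' @return A tibble with numeric score columns (`NA` = absent).
#' @export
read_splice_table <- function(path) {
  df <- read_tsv_chr(path)
  required_columns(df, c("cdna_hgvs", "ag", "al", "dg", "dl",
                         "ag_pos", "al_pos", "dg_pos", "dl_pos",
                         "maxent_ref", "maxent_var", "prior_severe"),
                   "splice-score table", path)
  if (!"maxent_delta" %in% names(df)) df$maxent_delta <- ""
  df |>
    dplyr::mutate(
      cdna_hgvs = normalize_hgvs(.data$cdna_hgvs),
      dplyr::across(dplyr::all_of(c("ag", "al", "dg", "dl",
                                    "ag_pos", "al_pos", "dg_pos", "dl_pos",
                                    "maxent_ref", "maxent_var",
                                    "maxent_delta")),
                    num_or_na),
      prior_severe = int_or_na(.data$prior_severe)
    )
}

#' Write a table as TSV
#'
#' Absent fields are written as empty strings so that write-then-read
#' round-trips exactly.
#'
#' @param df A tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table_tsv <- function(df, path) {
  readr::write_tsv(df, path, na = "")
  invisible(path)
}

#' Path to a packaged reference-cohort file
#'
#' @param file File name under the package's `extdata/` (default lists
#'   the available files).
#' @return A file path, or a vector of available file names.
#' @export
abca4_example <- function(file = NULL) {
  if (is.null(file)) {
    dir(system.file("extdata", package = "abca4cohort"))
  } else {
    system.file("extdata", file, package = "abca4cohort", mustWork = TRUE)
  }
}

#' Load the packaged 18-patient reference cohort
#'
#' @param config A [pipeline_config()].
#' @return A list of tibbles: `patients`, `variants`, `splice`.
#' @export
load_reference_cohort <- function(config = pipeline_config()) {
  list(
    patients = read_patient_table(abca4_example("table1_patients.tsv"), config),
    variants = read_variant_table(abca4_example("table1_variants.tsv")),
    splice = read_splice_table(abca4_example("table2_splice.tsv"))
  )
}
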