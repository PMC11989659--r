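# Visual acuity and phenotype severity.
#
# Best-corrected visual acuity (BCVA) is handled on the logMAR scale
# (higher = worse vision). Low-vision categories that have no letter
# score are mapped to fixed logMAR values: counting fingers (CF/FC,
# with or without a test distance such as "FC/40cm") -> 1.98, hand
# motion (HM) -> 2.28.
#
# Severity is graded from five clinical criteria (age of onset, BCVA in
# the better eye, fundus appearance type, autofluorescence type, ERG
# type). All inequalities are strict: onset exactly 15 or 10 years, or
# a better-eye acuity exactly at 0.78 or 1.0 logMAR, matches neither
# side.

#' Convert an acuity notation to logMAR
#'
#' @param raw Character vector: a decimal logMAR value (`"0.40"`), a
#'   counting-fingers code (`"CF"`, `"FC"`, optionally with a distance,
#'   e.g. `"FC/40cm"`), or hand motion (`"HM"`). Unrecognized notation
#'   is an error, never a silent default.
#' @param low_vision_codes Named numeric mapping for the low-vision
#'   categories.
#' @return Numeric vector of logMAR values in \[-0.3, 2.28\].
#' @examples
#' to_logmar(c("0.40", "FC/40cm", "HM"))
#' @export
to_logmar <- function(raw, low_vision_codes = c(CF = 1.98, HM = 2.28)) {
  stopifnot(is.character(raw) || is.numeric(raw))
  if (is.numeric(raw)) raw <- format(raw, trim = TRUE)
  out <- vapply(raw, function(x) {
    x <- trimws(x)
    if (!nzchar(x) || is.na(x)) {
      rlang::abort("empty acuity notation", class = "abca4_parse_error")
    }
    up <- toupper(x)
    if (grepl("^(CF|FC)(/.+)?$", up)) return(unname(low_vision_codes[["CF"]]))
    if (grepl("^HM(/.+)?$", up)) return(unname(low_vision_codes[["HM"]]))
    val <- suppressWarnings(as.numeric(x))
    if (is.na(val)) {
      rlang::abort(paste0("unrecognized acuity notation \"", x, "\""),
                   class = "abca4_parse_error")
    }
    if (val < -0.3 || val > 2.28) {
      rlang::abort(paste0("logMAR value out of range [-0.3, 2.28]: ", x),
                   class = "abca4_validation_error")
    }
    val
  }, numeric(1), USE.NAMES = FALSE)
  out
}

#' BCVA in the better eye
#'
#' The better eye is the one with the lower logMAR. If one eye is
#' absent the present eye is returned (with a message).
#'
#' @param od,os logMAR values for the right and left eye.
#' @return A single logMAR value, or `NA` if both are absent.
#' @export
better_eye <- function(od, os) {
  if (is.na(od) && is.na(os)) return(NA_real_)
  if (is.na(od) || is.na(os)) {
    message("better_eye: only one eye measured; using the available eye")
    return(if (is.na(od)) os else od)
  }
  min(od, os)
}

#' Classify phenotype severity from five clinical criteria
#'
#' Mild hits: onset > 15 years, better-eye BCVA < 0.78 logMAR, fundus
#' type 1, AF type 1, ERG type 1. Severe hits: onset < 10 years,
#' better-eye BCVA > 1.0 logMAR, fundus type 3, AF type 3, ERG type 3.
#' At least two hits on one side (and fewer than two on the other)
#' decide mild or severe; otherwise the patient is moderate. A record
#' with two or more hits on both sides is graded moderate with a
#' warning (a conflicting record). Missing type labels simply cannot
#' contribute hits; a missing onset or acuity makes the patient
#' unclassifiable.
#'
#' @param onset Age of onset in years.
#' @param better Better-eye BCVA (logMAR).
#' @param fundus,af,erg Optional type labels in `{1, 2, 3}`.
#' @return A list: `klass` (`"mild"`, `"moderate"`, `"severe"`, or
#'   `"unclassifiable"`), `grade` (1/2/3 or `NA`), `mild_hits`,
#'   `severe_hits`, `fields_available` (0-5).
#' @examples
#' classify_severity(onset = 7, better = 1.30, af = 1)
#' @export
classify_severity <- function(onset, better, fundus = NA, af = NA, erg = NA) {
  labels <- c(fundus = fundus, af = af, erg = erg)
  if (any(!is.na(labels) & !labels %in% 1:3)) {
    rlang::abort("type labels must be 1, 2, or 3",
                 class = "abca4_validation_error")
  }
  fields_available <- sum(!is.na(c(onset, better))) + sum(!is.na(labels))
  if (is.na(onset) || is.na(better)) {
    return(list(klass = "unclassifiable", grade = NA_integer_,
                mild_hits = NA_integer_, severe_hits = NA_integer_,
                fields_available = fields_available))
  }

  mild_hits <- sum(onset > 15, better < 0.78,
                   !is.na(labels) & labels == 1)
  severe_hits <- sum(onset < 10, better > 1.0,
                     !is.na(labels) & labels == 3)

  if (mild_hits >= 2L && severe_hits >= 2L) {
    rlang::warn("conflicting record: >=2 mild and >=2 severe criteria met; grading moderate")
    klass <- "moderate"
  } else if (mild_hits >= 2L) {
    klass <- "mild"
  } else if (severe_hits >= 2L) {
    klass <- "severe"
  } else {
    klass <- "moderate"
  }
  grade <- c(mild = 1L, moderate = 2L, severe = 3L)[[klass]]
  list(klass = klass, grade = grade, mild_hits = as.integer(mild_hits),
       severe_hits = as.integer(severe_hits),
       fields_available = as.integer(fields_available))
}
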