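# In-silico splice decision rules for non-canonical intronic variants.
#
# Two lines of evidence are combined:
#   * SpliceAI delta scores (four channels, each in [0,1]); the maximum
#     channel is called pathogenic at >= delta_threshold (default 0.2).
#   * For variants inside a functional donor/acceptor site, a MaxEntScan
#     score difference (variant - reference) strictly below zero marks a
#     loss of the site. Deep intronic variants never trigger this branch.
# Running SpliceAI or MaxEntScan themselves is out of scope; their
# scores arrive precomputed in the splice-score table.

DELTA_CHANNELS <- c("acceptor_gain", "acceptor_loss", "donor_gain", "donor_loss")

#' MaxEntScan score difference
#'
#' Computes the splice-site strength change as variant score minus
#' reference score (both in bits). A negative value within a functional
#' site indicates loss of the site.
#'
#' @param reference,variant MaxEntScan scores; `NA` marks an absent score.
#' @return `variant - reference`, or `NA_real_` when either score is
#'   absent (never silently zero).
#' @examples
#' delta_maxent(8.702, 5.000)
#' @export
delta_maxent <- function(reference, variant) {
  if (is.null(reference) || is.null(variant) ||
      is.na(reference) || is.na(variant)) {
    return(NA_real_)
  }
  variant - reference
}

#' Construct a splice prediction record
#'
#' @param acceptor_gain,acceptor_loss,donor_gain,donor_loss SpliceAI
#'   delta scores in \[0,1\]; an absent channel (`NA`) is treated as no
#'   evidence (0) when taking the maximum.
#' @param positions Optional named integer vector of delta positions (bp).
#' @param maxent_reference,maxent_variant Optional MaxEntScan scores.
#' @param maxent_delta Optional precomputed score difference; used only
#'   when the reference/variant pair is absent (published tables often
#'   print only the difference).
#' @param prior_severe_phenotype Logical: the variant has a reported
#'   association with a severe clinical phenotype in prior studies.
#' @return An object of class `splice_prediction`.
#' @export
splice_prediction <- function(acceptor_gain = NA_real_, acceptor_loss = NA_real_,
                              donor_gain = NA_real_, donor_loss = NA_real_,
                              positions = NULL,
                              maxent_reference = NA_real_,
                              maxent_variant = NA_real_,
                              maxent_delta = NA_real_,
                              prior_severe_phenotype = FALSE) {
  deltas <- c(
    acceptor_gain = acceptor_gain, acceptor_loss = acceptor_loss,
    donor_gain = donor_gain, donor_loss = donor_loss
  )
  bad <- !is.na(deltas) & (deltas < 0 | deltas > 1)
  if (any(bad)) {
    rlang::abort(
      paste0("delta scores must lie in [0,1]: ",
             paste(names(deltas)[bad], collapse = ", ")),
      class = "abca4_validation_error"
    )
  }
  dmx <- if (!is.na(maxent_reference) && !is.na(maxent_variant)) {
    delta_maxent(maxent_reference, maxent_variant)
  } else {
    maxent_delta
  }
  structure(
    list(
      delta_scores = deltas, delta_positions = positions,
      maxent_reference = maxent_reference, maxent_variant = maxent_variant,
      maxent_delta = dmx,
      prior_severe_phenotype = isTRUE(prior_severe_phenotype)
    ),
    class = "splice_prediction"
  )
}

#' Call the splice effect of a variant
#'
#' The maximum of the four delta channels is taken; when it reaches
#' `delta_threshold` (>=, so a score exactly at the threshold is a call)
#' the effect follows the dominant channel (loss channels give
#' `loss_of_site`, gain channels `gain_of_site`). Independently, a
#' variant inside a functional splice site with a strictly negative
#' MaxEntScan difference is called `loss_of_site` (a difference of
#' exactly zero is not a loss). Otherwise `no_predicted_effect`.
#'
#' @param p A `splice_prediction`.
#' @param delta_threshold Delta-score call threshold in (0,1); default 0.2.
#' @param in_functional_site Logical: the variant lies within a known
#'   functional donor/acceptor sequence (near-splice, not deep intronic);
#'   gates the MaxEntScan branch.
#' @return An object of class `splice_call`: `effect` (one of
#'   `loss_of_site`, `gain_of_site`, `no_predicted_effect`),
#'   `dominant_channel`, `delta_max`, `delta_maxent`.
#' @examples
#' p <- splice_prediction(acceptor_loss = 0.42, maxent_delta = -3.702)
#' call_splice_effect(p, in_functional_site = TRUE)
#' @export
call_splice_effect <- function(p, delta_threshold = 0.2,
                               in_functional_site = FALSE) {
  stopifnot(inherits(p, "splice_prediction"),
            delta_threshold > 0, delta_threshold < 1)
  deltas <- p$delta_scores
  filled <- ifelse(is.na(deltas), 0, deltas)
  dominant <- DELTA_CHANNELS[which.max(filled)]
  delta_max <- max(filled)

  effect <- "no_predicted_effect"
  if (delta_max >= delta_threshold) {
    effect <- if (dominant %in% c("acceptor_loss", "donor_loss")) {
      "loss_of_site"
    } else {
      "gain_of_site"
    }
  } else if (in_functional_site && !is.na(p$maxent_delta) &&
             p$maxent_delta < 0) {
    effect <- "loss_of_site"
  }

  structure(
    list(
      effect = effect, dominant_channel = dominant,
      delta_max = delta_max, delta_maxent = p$maxent_delta
    ),
    class = "splice_call"
  )
}

#' @export
print.splice_call <- function(x, ...) {
  cat("<splice_call> ", x$effect, " (", x$dominant_channel, " ",
      format(x$delta_max), ")\n", sep = "")
  invisible(x)
}

# Build a splice_prediction from one row of the splice-score table.
splice_prediction_from_row <- function(row) {
  num <- function(v) if (is.null(v) || is.na(v)) NA_real_ else as.numeric(v)
  splice_prediction(
    acceptor_gain = num(row$ag), acceptor_loss = num(row$al),
    donor_gain = num(row$dg), donor_loss = num(row$dl),
    positions = c(
      acceptor_gain = num(row$ag_pos), acceptor_loss = num(row$al_pos),
      donor_gain = num(row$dg_pos), donor_loss = num(row$dl_pos)
    ),
    maxent_reference = num(row$maxent_ref),
    maxent_variant = num(row$maxent_var),
    maxent_delta = num(row$maxent_delta),
    prior_severe_phenotype = identical(as.integer(row$prior_severe), 1L)
  )
}
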