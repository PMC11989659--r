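# Allele deleteriousness and genotype groups A/B/C.
#
# Deleterious ("null") alleles are those expected to abolish gene
# product function under the ACMG very-strong (PVS1-class) logic:
# nonsense, frameshift, canonical +/-1/2 splice site, initiation-codon
# loss, and exonic deletions. Non-canonical intronic alleles are
# deleterious only on in-silico splice evidence or on reported prior
# association with a severe phenotype. Missense and in-frame indels are
# mild. Grouping then counts alleles (a homozygous variant contributes
# two): >=2 deleterious -> C; exactly one deleterious plus >=1 mild ->
# B; >=2 mild and no deleterious -> A. Phase is not modeled; single-het
# patients are unassigned and excluded from group statistics.

NULL_VARIANT_CLASSES <- c(
  "nonsense", "frameshift", "canonical_splice", "start_loss", "cnv_deletion"
)

#' Classify one allele as deleterious or mild
#'
#' @param consequence Consequence class from [infer_consequence()].
#' @param splice_effect For `near_splice_intronic`/`deep_intronic`
#'   alleles, the `effect` of a [call_splice_effect()] result (or the
#'   `splice_call` itself); `NULL` when no prediction exists.
#' @param prior_severe Logical: prior studies tie this variant to a
#'   severe phenotype, which makes it deleterious irrespective of the
#'   in-silico call.
#' @return A list with `category` (`deleterious` or `non_deleterious`)
#'   and `basis` (one of `null_variant_class`, `splice_prediction`,
#'   `prior_phenotype_evidence`, `missense_or_inframe`,
#'   `deep_intronic_unsupported`).
#' @export
assign_allele_severity <- function(consequence, splice_effect = NULL,
                                   prior_severe = FALSE) {
  if (inherits(splice_effect, "splice_call")) {
    splice_effect <- splice_effect$effect
  }
  sev <- function(category, basis) list(category = category, basis = basis)

  if (consequence %in% NULL_VARIANT_CLASSES) {
    return(sev("deleterious", "null_variant_class"))
  }
  if (consequence %in% c("missense", "inframe_indel", "other")) {
    return(sev("non_deleterious", "missense_or_inframe"))
  }
  if (consequence %in% c("near_splice_intronic", "deep_intronic")) {
    if (isTRUE(prior_severe)) {
      return(sev("deleterious", "prior_phenotype_evidence"))
    }
    if (is.null(splice_effect)) {
      if (consequence == "near_splice_intronic") {
        rlang::abort(
          "missing splice evidence for a near-splice intronic allele; the call changes genotype grouping",
          class = "abca4_missing_evidence_error"
        )
      }
      return(sev("non_deleterious", "deep_intronic_unsupported"))
    }
    if (splice_effect %in% c("loss_of_site", "gain_of_site")) {
      return(sev("deleterious", "splice_prediction"))
    }
    return(sev("non_deleterious", "splice_prediction"))
  }
  rlang::abort(paste0("unknown consequence class \"", consequence, "\""),
               class = "abca4_validation_error")
}

#' Assign a patient to genotype group A, B, or C
#'
#' @param categories Character vector of per-variant allele categories
#'   (`deleterious` / `non_deleterious`).
#' @param zygosity Character vector (`het` / `hom`) parallel to
#'   `categories`; a homozygous variant contributes two alleles.
#' @return A list with `group` (`A`, `B`, `C`, or `unassigned`),
#'   `n_deleterious_alleles`, `n_mild_alleles`, `total_alleles`.
#' @examples
#' assign_genotype_group(c("deleterious", "non_deleterious"), c("het", "het"))
#' @export
assign_genotype_group <- function(categories, zygosity) {
  if (length(categories) == 0L) {
    rlang::abort("a patient needs at least one detected allele",
                 class = "abca4_validation_error")
  }
  stopifnot(length(categories) == length(zygosity))
  if (!all(categories %in% c("deleterious", "non_deleterious"))) {
    rlang::abort("allele categories must be deleterious/non_deleterious",
                 class = "abca4_validation_error")
  }
  if (!all(zygosity %in% c("het", "hom"))) {
    rlang::abort("zygosity must be het or hom",
                 class = "abca4_validation_error")
  }
  dose <- ifelse(zygosity == "hom", 2L, 1L)
  n_del <- sum(dose[categories == "deleterious"])
  n_mild <- sum(dose[categories == "non_deleterious"])
  total <- n_del + n_mild

  group <- if (total < 2L) {
    "unassigned"
  } else if (n_del >= 2L) {
    "C"
  } else if (n_del == 1L) {
    "B"
  } else {
    "A"
  }
  list(
    group = group, n_deleterious_alleles = n_del,
    n_mild_alleles = n_mild, total_alleles = total
  )
}
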