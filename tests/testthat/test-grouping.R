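# Allele deleteriousness and genotype groups A/B/C.

test_that("null-class consequences are deleterious, missense-class mild", {
  for (cons in c("nonsense", "frameshift", "canonical_splice", "start_loss",
                 "cnv_deletion")) {
    s <- assign_allele_severity(cons)
    expect_equal(s$category, "deleterious", info = cons)
    expect_equal(s$basis, "null_variant_class", info = cons)
  }
  for (cons in c("missense", "inframe_indel")) {
    s <- assign_allele_severity(cons)
    expect_equal(s$category, "non_deleterious", info = cons)
  }
})

test_that("intronic alleles follow splice evidence and prior phenotype", {
  loss <- assign_allele_severity("near_splice_intronic",
                                 splice_effect = "loss_of_site")
  expect_equal(loss$category, "deleterious")
  expect_equal(loss$basis, "splice_prediction")

  quiet <- assign_allele_severity("deep_intronic",
                                  splice_effect = "no_predicted_effect")
  expect_equal(quiet$category, "non_deleterious")

  prior <- assign_allele_severity("near_splice_intronic",
                                  splice_effect = "no_predicted_effect",
                                  prior_severe = TRUE)
  expect_equal(prior$category, "deleterious")
  expect_equal(prior$basis, "prior_phenotype_evidence")

  unsupported <- assign_allele_severity("deep_intronic")
  expect_equal(unsupported$category, "non_deleterious")
  expect_equal(unsupported$basis, "deep_intronic_unsupported")

  expect_error(assign_allele_severity("near_splice_intronic"),
               class = "abca4_missing_evidence_error")
})

test_that("genotype grouping matches the worked patient examples", {
  # two het missense
  expect_equal(assign_genotype_group(rep("non_deleterious", 2),
                                     rep("het", 2))$group, "A")
  # het nonsense + het missense
  expect_equal(assign_genotype_group(c("deleterious", "non_deleterious"),
                                     c("het", "het"))$group, "B")
  # homozygous canonical-splice
  g <- assign_genotype_group("deleterious", "hom")
  expect_equal(g$group, "C")
  expect_equal(g$total_alleles, 2L)
  # three variants: nonsense + deleterious intronic + missense
  expect_equal(assign_genotype_group(
    c("deleterious", "deleterious", "non_deleterious"), rep("het", 3)
  )$group, "C")
  # homozygous missense
  expect_equal(assign_genotype_group("non_deleterious", "hom")$group, "A")
  # single het allele
  expect_equal(assign_genotype_group("deleterious", "het")$group, "unassigned")
  expect_error(assign_genotype_group(character(0), character(0)),
               class = "abca4_validation_error")
})

test_that("grouping agrees with the brute-force oracle on all small multisets", {
  alleles <- expand.grid(
    category = c("deleterious", "non_deleterious"),
    zygosity = c("het", "hom"),
    stringsAsFactors = FALSE
  )
  n_checked <- 0L
  for (size in 1:4) {
    idx <- do.call(expand.grid, rep(list(seq_len(nrow(alleles))), size))
    for (r in seq_len(nrow(idx))) {
      pick <- alleles[as.integer(idx[r, ]), ]
      got <- assign_genotype_group(pick$category, pick$zygosity)
      want <- oracle_group(pick$category, pick$zygosity)
      expect_equal(got$group, want,
                   info = paste(pick$category, pick$zygosity, collapse = "; "))
      expect_equal(got$n_deleterious_alleles + got$n_mild_alleles,
                   got$total_alleles)
      n_checked <- n_checked + 1L
    }
  }
  expect_equal(n_checked, 4L + 16L + 64L + 256L)
})

test_that("promoting an allele to deleterious never moves the group toward A", {
  rank <- c(A = 1L, B = 2L, C = 3L)
  set.seed(7)
  for (rep in 1:200) {
    size <- sample(2:4, 1)
    categories <- sample(c("deleterious", "non_deleterious"), size,
                         replace = TRUE)
    zygosity <- sample(c("het", "hom"), size, replace = TRUE)
    before <- assign_genotype_group(categories, zygosity)$group
    i <- sample(seq_len(size), 1)
    promoted <- categories
    promoted[i] <- "deleterious"
    after <- assign_genotype_group(promoted, zygosity)$group
    if (before %in% names(rank) && after %in% names(rank)) {
      expect_gte(rank[[after]], rank[[before]])
    }
  }
})

test_that("the reference cohort reproduces every printed genotype group", {
  merged <- dplyr::inner_join(
    ref_result$assignments,
    ref_cohort$patients[, c("patient_id", "reported_group")],
    by = "patient_id"
  )
  expect_equal(nrow(merged), 18L)
  expect_identical(merged$group, merged$reported_group)
})
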