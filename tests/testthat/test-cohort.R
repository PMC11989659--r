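# Cohort summary statistics, occurrence counts, and region tallies.

test_that("the reference cohort reproduces the published onset and acuity statistics", {
  s <- ref_result$summary
  expect_equal(s$n_patients, 18L)
  expect_equal(s$n_adult, 6L)
  expect_equal(s$n_child, 12L)
  expect_equal(round(s$onset_mean_adult, 1), 44.3)
  expect_equal(round(s$onset_mean_child, 1), 9.6)
  expect_equal(s$n_late_onset, 4L)
  expect_equal(round(s$mean_logmar_od, 2), 0.96)
  expect_equal(s$logmar_range, c(0, 1.98))
})

test_that("group-level statistics match the printed central values and ranges", {
  gs <- ref_result$summary$group_stats
  b <- gs[gs$group == "B", ]
  expect_equal(round(b$onset_mean, 1), 18.5)
  expect_equal(c(b$onset_min, b$onset_max), c(6, 55))
  expect_equal(round(b$bcva_mean_all_eyes, 3), 0.878)
  c_ <- gs[gs$group == "C", ]
  expect_equal(round(c_$onset_mean, 1), 10.4)
  expect_equal(c(c_$onset_min, c_$onset_max), c(7, 25))
  expect_equal(round(c_$bcva_mean_all_eyes, 3), 1.113)
  expect_equal(c_$n_eyes, 14L)
  a <- gs[gs$group == "A", ]
  expect_equal(round(a$onset_mean, 1), 39.4)
  expect_equal(c(a$onset_min, a$onset_max), c(11, 52))
})

test_that("AF distribution, zygosity breakdown, and crosstab match the publication", {
  s <- ref_result$summary
  expect_equal(unname(s$af_counts), c(4L, 6L, 4L))
  expect_equal(s$n_af_available, 14L)
  expect_equal(unname(s$zygosity_counts[c("biallelic_het", "homozygous",
                                          "triallelic")]),
               c(14L, 3L, 1L))
  expect_equal(unname(s$group_counts), c(5L, 6L, 7L))
  expect_equal(unname(s$severity_counts), c(4L, 5L, 6L))
  expect_equal(s$n_evaluable, 15L)
  ct <- s$crosstab
  expect_equal(unname(unlist(ct[ct$group == "A", -1])), c(3L, 0L, 1L))
  expect_equal(unname(unlist(ct[ct$group == "B", -1])), c(1L, 3L, 1L))
  expect_equal(unname(unlist(ct[ct$group == "C", -1])), c(0L, 2L, 4L))
})

test_that("strata partition the cohort and group percentages sum to 100", {
  s <- ref_result$summary
  expect_equal(s$n_adult + s$n_child, s$n_patients)
  expect_equal(sum(s$group_percent), 100)
  expect_equal(sum(s$af_counts), s$n_af_available)
})

test_that("all-eye group means equal the patient-weighted recomputation", {
  pg <- dplyr::inner_join(ref_cohort$patients, ref_result$assignments,
                          by = "patient_id")
  for (g in c("A", "B", "C")) {
    sub <- pg[pg$group == g, ]
    brute <- mean(c(sub$logmar_od, sub$logmar_os))
    weighted <- stats::weighted.mean((sub$logmar_od + sub$logmar_os) / 2,
                                     rep(2, nrow(sub)))
    gs <- ref_result$summary$group_stats
    expect_equal(gs$bcva_mean_all_eyes[gs$group == g], brute)
    expect_equal(brute, weighted)
  }
})

test_that("a single-patient cohort summarizes to its own values", {
  patients <- tibble::tibble(
    patient_id = "X1", sex = "F", onset_age = 50, exam_age = 51,
    acuity_od = "0.5", acuity_os = "0.5", logmar_od = 0.5, logmar_os = 0.5,
    better_eye_logmar = 0.5, fundus_type = NA_integer_,
    af_type = NA_integer_, erg_type = NA_integer_, evaluable = TRUE,
    reported_group = NA_character_, reported_severity = NA_integer_
  )
  variants <- tibble::tibble(
    patient_id = "X1", cdna_hgvs = c("c.71G>A", "c.1804C>T"),
    protein_hgvs = c("p.Arg24His", "p.Arg602Trp"), genomic_region = "",
    zygosity = "het", novel = 0L
  )
  ann <- annotate_variants(variants)
  s <- summarize_cohort(patients, ann, assign_genotype_groups(ann),
                        tibble::tibble(patient_id = "X1", grade = NA_integer_))
  expect_equal(s$onset_mean_adult, 50)
  expect_true(is.na(s$onset_mean_child))
  expect_equal(s$mean_logmar_od, 0.5)
  expect_equal(unname(s$group_counts), c(1L, 0L, 0L))
  expect_error(summarize_cohort(patients[0, ], ann,
                                assign_genotype_groups(ann),
                                tibble::tibble()),
               class = "abca4_validation_error")
})

test_that("occurrence counting distinguishes carriers from allele copies", {
  ann <- ref_result$annotated
  expect_equal(occurrence_count(ann, "c.2894A>G"), 3L)
  expect_equal(occurrence_count(ann, "c.2919-1G>A"), 1L)
  expect_equal(occurrence_count(ann, "c.2919-1G>A", mode = "alleles"), 2L)
  expect_equal(occurrence_count(ann, "c.9999A>G"), 0L)
  expect_equal(occurrence_count(ann, "c.4217A>G"), 2L)
  expect_equal(occurrence_count(ann, "c.4217A>G", mode = "alleles"), 3L)
})

test_that("the variant spectrum of an empty table is all zeros", {
  empty <- tibble::tibble(key = character(), consequence = character(),
                          novel = integer())
  spec <- variant_spectrum(empty)
  expect_true(all(spec$spectrum == 0L))
  expect_equal(spec$n_novel, 0L)
})

test_that("region tallies place variants in exons, introns, and domains", {
  model <- toy_gene_model()
  vs <- list(
    variant_descriptor(cdna_hgvs = "c.150A>G", protein_hgvs = "p.Ala50Gly"),
    variant_descriptor(cdna_hgvs = "c.100+5G>A"),
    variant_descriptor(cdna_hgvs = "c.101-8G>A"),
    variant_descriptor(cdna_hgvs = "c.24G>A", protein_hgvs = "p.Arg24His")
  )
  tally <- region_tally(vs, model)
  expect_equal(tally$exons$n, c(1L, 1L))
  expect_equal(tally$introns$n, 2L)  # +5 after exon 1, -8 before exon 2
  expect_equal(tally$domains$n[tally$domains$domain == "ECD1"], 2L)
  expect_equal(nrow(tally$unlocatable), 0L)

  expect_warning(
    far <- region_tally(list(variant_descriptor(cdna_hgvs = "c.999G>A")),
                        model),
    "could not be located"
  )
  expect_equal(far$unlocatable$key, "c.999G>A")
})

test_that("gene-model invariants are enforced on read", {
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(
    list(transcript = "BAD", exons = list(
      list(index = 1, cdna_start = 1, cdna_end = 100),
      list(index = 2, cdna_start = 150, cdna_end = 200)
    ), domains = list()),
    path, auto_unbox = TRUE
  )
  expect_error(read_gene_model(path), "contiguous",
               class = "abca4_validation_error")
})

test_that("the packaged synthetic gene model locates the whole reference spectrum", {
  model <- read_gene_model(abca4_example("synthetic_gene_model.json"))
  distinct_idx <- !duplicated(ref_result$annotated$key)
  descriptors <- attr(ref_result$annotated, "descriptors")[distinct_idx]
  expect_warning(tally <- region_tally(descriptors, model), "located")
  # unlocatable: the genomic-only CNV, plus one acceptor-side intronic
  # variant whose anchor falls inside the toy model's first exon (there
  # is no intron upstream of it on this invented exon layout)
  expect_equal(nrow(tally$unlocatable), 2L)
  expect_equal(sum(tally$exons$n) + sum(tally$introns$n), 28L)
})

test_that("known print/recompute discrepancies are surfaced, not forced", {
  rep <- reference_discrepancy_report(ref_result$summary)
  expect_equal(nrow(rep), 4L)
  expect_false(any(rep$consistent))
  expect_equal(rep$recomputed[rep$quantity == "distinct variant total"], 30)
})
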