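# Shared fixtures: the packaged 18-patient reference cohort, loaded once,
# and small builders used across test files.

ref_cohort <- load_reference_cohort()

ref_result <- run_pipeline(ref_cohort$patients, ref_cohort$variants,
                           ref_cohort$splice)

# Brute-force genotype-group oracle written directly from the three
# grouping clauses: count alleles (hom = 2); >=2 deleterious -> C;
# exactly 1 deleterious with >=1 mild -> B; no deleterious and >=2 mild
# -> A; fewer than 2 alleles -> unassigned.
oracle_group <- function(categories, zygosity) {
  doses <- ifelse(zygosity == "hom", 2L, 1L)
  ndel <- sum(doses[categories == "deleterious"])
  nmild <- sum(doses[categories == "non_deleterious"])
  if (ndel + nmild < 2L) return("unassigned")
  if (ndel >= 2L) return("C")
  if (ndel == 1L && nmild >= 1L) return("B")
  if (ndel == 0L && nmild >= 2L) return("A")
  stop("unreachable")
}

# A two-exon, 100-nt-each toy gene model (via JSON so the reader runs).
toy_gene_model <- function(domains = list(list(name = "ECD1", aa_start = 1,
                                               aa_end = 500))) {
  path <- withr::local_tempfile(fileext = ".json",
                                .local_envir = parent.frame())
  jsonlite::write_json(
    list(
      transcript = "TOY-1",
      exons = list(
        list(index = 1, cdna_start = 1, cdna_end = 100),
        list(index = 2, cdna_start = 101, cdna_end = 200)
      ),
      domains = domains
    ),
    path, auto_unbox = TRUE
  )
  read_gene_model(path)
}

# Write a simulated cohort to disk and read it back through the package
# readers (exercises the IO layer on the way).
roundtrip_sim <- function(sim, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  write_table_tsv(sim$patients, file.path(dir, "patients.tsv"))
  write_table_tsv(sim$variants, file.path(dir, "variants.tsv"))
  write_table_tsv(sim$splice, file.path(dir, "splice.tsv"))
  list(
    patients = read_patient_table(file.path(dir, "patients.tsv")),
    variants = read_variant_table(file.path(dir, "variants.tsv")),
    splice = read_splice_table(file.path(dir, "splice.tsv"))
  )
}
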