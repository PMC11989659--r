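# HGVS parsing, formatting, and consequence inference.

test_that("cDNA parsing decomposes substitutions, indels, and intronic offsets", {
  cases <- list(
    list("c.71G>A", 71L, 0L, "substitution", "G", "A"),
    list("c.1937+392G>A", 1937L, 392L, "substitution", "G", "A"),
    list("c.6006-3C>A", 6006L, -3L, "substitution", "C", "A"),
    list("c.5554del", 5554L, 0L, "deletion", "", ""),
    list("c.260dup", 260L, 0L, "duplication", "", "")
  )
  for (cs in cases) {
    x <- parse_cdna(cs[[1]])
    expect_equal(x$anchor_position, cs[[2]], info = cs[[1]])
    expect_equal(x$intron_offset, cs[[3]], info = cs[[1]])
    expect_equal(x$edit_kind, cs[[4]], info = cs[[1]])
    expect_equal(x$ref_allele, cs[[5]], info = cs[[1]])
    expect_equal(x$alt_allele, cs[[6]], info = cs[[1]])
  }
  rng <- parse_cdna("c.100_102delinsTT")
  expect_equal(rng$edit_kind, "delins")
  expect_equal(rng$anchor_end, 102L)
})

test_that("malformed or unsupported cDNA strings fail loudly", {
  expect_error(parse_cdna("g.123A>G"), class = "abca4_parse_error")
  expect_error(parse_cdna("c.xyz"), class = "abca4_parse_error")
  expect_error(parse_cdna("c.123inv"), "unsupported",
               class = "abca4_parse_error")
  expect_error(parse_cdna("c.123"), class = "abca4_parse_error")
  expect_error(parse_cdna("c.123AA>GG"), class = "abca4_parse_error")
})

test_that("protein parsing recognizes missense, stop, and frameshift tokens", {
  x <- parse_protein("p.Arg24His")
  expect_equal(x[c("ref_residue", "residue_number", "alt_residue")],
               list(ref_residue = "Arg", residue_number = 24L,
                    alt_residue = "His"))
  expect_false(x$frameshift)

  x <- parse_protein("p.Val460Ter")
  expect_equal(x$alt_residue, "Ter")
  expect_false(x$frameshift)

  x <- parse_protein("p.Leu2230ProfsTer17")
  expect_true(x$frameshift)
  expect_equal(x$alt_residue, "Pro")
  expect_equal(x$fs_ter_distance, 17L)

  expect_error(parse_protein("p.Xyz12Gln"), class = "abca4_parse_error")
  expect_error(parse_protein("Arg24His"), class = "abca4_parse_error")
})

test_that("parse-then-format round-trips every reference-cohort notation", {
  v <- ref_cohort$variants
  for (s in v$cdna_hgvs[nzchar(v$cdna_hgvs)]) {
    expect_identical(format_cdna(parse_cdna(s)), s, info = s)
  }
  for (s in v$protein_hgvs[nzchar(v$protein_hgvs)]) {
    expect_identical(format_protein(parse_protein(s)), s, info = s)
  }
  for (s in v$genomic_region[nzchar(v$genomic_region)]) {
    expect_identical(format_genomic_region(parse_genomic_region(s)), s,
                     info = s)
  }
})

test_that("consequence inference follows protein first, then intron offset", {
  expect_equal(infer_consequence(protein = parse_protein("p.Trp1618Ter")),
               "nonsense")
  expect_equal(infer_consequence(cdna = parse_cdna("c.2919-1G>A")),
               "canonical_splice")
  expect_equal(infer_consequence(cdna = parse_cdna("c.2160+782T>C")),
               "deep_intronic")
  expect_equal(infer_consequence(cdna = parse_cdna("c.4253+5G>A")),
               "near_splice_intronic")
  expect_equal(
    infer_consequence(genomic = parse_genomic_region("chr1:94480267-94482198del")),
    "cnv_deletion"
  )
  # deletion annotated with a direct stop reads as nonsense
  expect_equal(
    infer_consequence(cdna = parse_cdna("c.1378del"),
                      protein = parse_protein("p.Val460Ter")),
    "nonsense"
  )
  expect_equal(
    infer_consequence(protein = parse_protein("p.Met1Leu")),
    "start_loss"
  )
  expect_error(infer_consequence(), class = "abca4_unclassifiable_error")
})

test_that("the near-splice window is configurable and bounded below", {
  cd <- parse_cdna("c.4253+5G>A")
  expect_equal(infer_consequence(cdna = cd, near_splice_window = 4L),
               "deep_intronic")
  expect_equal(infer_consequence(cdna = cd, near_splice_window = 5L),
               "near_splice_intronic")
  expect_error(infer_consequence(cdna = cd, near_splice_window = 2L))
})

test_that("consequence is invariant to whitespace and unicode dashes", {
  expect_equal(
    variant_descriptor(cdna_hgvs = " c.6006−3C>A ")$consequence,
    variant_descriptor(cdna_hgvs = "c.6006-3C>A")$consequence
  )
  expect_identical(normalize_hgvs("c.6006–3C>A"), "c.6006-3C>A")
})

test_that("the reference cohort yields the expected consequence spectrum", {
  spec <- variant_spectrum(ref_result$annotated)
  expect_equal(spec$spectrum[["nonsense"]], 6L)
  expect_equal(spec$spectrum[["frameshift"]], 5L)
  expect_equal(spec$spectrum[["canonical_splice"]], 4L)
  expect_equal(spec$spectrum[["near_splice_intronic"]], 2L)
  expect_equal(spec$spectrum[["deep_intronic"]], 2L)
  expect_equal(spec$spectrum[["cnv_deletion"]], 1L)
  expect_equal(spec$spectrum[["missense"]], 10L)
  expect_equal(spec$n_distinct, 30L)
})
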