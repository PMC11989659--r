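# HGVS parsing and consequence inference.
#
# Coordinates are taken at face value: cDNA positions are 1-based
# coding-sequence positions, intronic positions are written as
# exon-anchor +/- offset, genomic regions are 1-based inclusive.
# No genome-to-transcript projection or reference-sequence validation
# is performed.

AA3 <- c(
  "Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His", "Ile",
  "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp", "Tyr", "Val",
  "Ter"
)

CONSEQUENCE_LEVELS <- c(
  "missense", "nonsense", "frameshift", "inframe_indel", "canonical_splice",
  "near_splice_intronic", "deep_intronic", "cnv_deletion", "start_loss",
  "other"
)

parse_error <- function(msg, text = NULL) {
  rlang::abort(
    c(msg, if (!is.null(text)) paste0("in: ", text)),
    class = "abca4_parse_error"
  )
}

#' Normalize an HGVS-bearing string
#'
#' Trims whitespace, removes internal spaces, and converts Unicode
#' dash/minus characters (en/em dash, true minus) to the ASCII hyphen so
#' that copy-pasted notation parses uniformly.
#'
#' @param x Character vector.
#' @return Character vector of the same length.
#' @export
normalize_hgvs <- function(x) {
  x <- gsub("[−‐‑‒–—]", "-", x)
  x <- gsub("\\s+", "", x)
  x
}

#' Parse a cDNA HGVS string
#'
#' Supports the edit kinds used in clinical variant tables: substitution
#' (`c.71G>A`), deletion (`c.5554del`), duplication (`c.260dup`),
#' insertion (`c.100_101insA`), and deletion-insertion
#' (`c.100_102delinsTT`), at exonic positions or intronic offsets
#' (`c.1937+392G>A`, `c.6006-3C>A`). Unsupported constructs fail loudly;
#' there is no best-effort guessing.
#'
#' @param text A single HGVS string beginning with `"c."`.
#' @return An object of class `cdna_change` with fields
#'   `anchor_position`, `intron_offset`, `anchor_end`, `end_offset`
#'   (for ranged edits, otherwise `NA`), `edit_kind`, `ref_allele`,
#'   `alt_allele`.
#' @examples
#' parse_cdna("c.6006-3C>A")
#' parse_cdna("c.5554del")
#' @export
parse_cdna <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  raw <- text
  text <- normalize_hgvs(text)
  if (!startsWith(text, "c.")) {
    parse_error("cDNA HGVS must begin with \"c.\"", raw)
  }
  body <- substring(text, 3L)

  pos_re <- "(\\d+)([+-]\\d+)?"
  m <- regexec(paste0("^", pos_re, "(?:_", pos_re, ")?(.*)$"), body)
  parts <- regmatches(body, m)[[1]]
  if (length(parts) == 0L || parts[[2]] == "") {
    parse_error("could not read a cDNA position", raw)
  }
  anchor <- as.integer(parts[[2]])
  offset <- if (parts[[3]] == "") 0L else as.integer(parts[[3]])
  anchor_end <- if (parts[[4]] == "") NA_integer_ else as.integer(parts[[4]])
  end_offset <- if (parts[[5]] == "") {
    if (is.na(anchor_end)) NA_integer_ else 0L
  } else {
    as.integer(parts[[5]])
  }
  edit <- parts[[6]]
  if (anchor < 1L) parse_error("cDNA anchor position must be >= 1", raw)
  if (!is.na(anchor_end) && anchor_end < anchor) {
    parse_error("range end precedes range start", raw)
  }

  nt <- "[ACGTacgt]"
  kind <- ref <- alt <- NULL
  if (grepl(paste0("^", nt, ">", nt, "$"), edit)) {
    kind <- "substitution"
    ref <- toupper(substring(edit, 1L, 1L))
    alt <- toupper(substring(edit, 3L, 3L))
    if (!is.na(anchor_end)) {
      parse_error("a substitution cannot span a range", raw)
    }
  } else if (grepl(paste0("^delins", nt, "+$"), edit)) {
    kind <- "delins"
    ref <- ""
    alt <- toupper(substring(edit, 7L))
  } else if (grepl(paste0("^del", nt, "*$"), edit)) {
    kind <- "deletion"
    ref <- toupper(substring(edit, 4L))
    alt <- ""
  } else if (grepl(paste0("^dup", nt, "*$"), edit)) {
    kind <- "duplication"
    ref <- toupper(substring(edit, 4L))
    alt <- ""
  } else if (grepl(paste0("^ins", nt, "+$"), edit)) {
    kind <- "insertion"
    ref <- ""
    alt <- toupper(substring(edit, 4L))
    if (is.na(anchor_end)) {
      parse_error("an insertion requires a two-position range", raw)
    }
  } else if (edit == "") {
    parse_error("position given but no edit", raw)
  } else {
    parse_error(
      paste0("unsupported cDNA edit \"", edit, "\""), raw
    )
  }

  structure(
    list(
      anchor_position = anchor, intron_offset = offset,
      anchor_end = anchor_end, end_offset = end_offset,
      edit_kind = kind, ref_allele = ref, alt_allele = alt
    ),
    class = "cdna_change"
  )
}

#' Format a cDNA change back to HGVS notation
#'
#' Inverse of [parse_cdna()]; `format_cdna(parse_cdna(x))` reproduces the
#' normalized form of `x`.
#'
#' @param x A `cdna_change`.
#' @return A single HGVS `"c."` string.
#' @export
format_cdna <- function(x) {
  stopifnot(inherits(x, "cdna_change"))
  fmt_pos <- function(pos, off) {
    paste0(pos, if (off > 0L) paste0("+", off) else if (off < 0L) off else "")
  }
  loc <- fmt_pos(x$anchor_position, x$intron_offset)
  if (!is.na(x$anchor_end)) {
    loc <- paste0(loc, "_", fmt_pos(x$anchor_end, x$end_offset))
  }
  edit <- switch(x$edit_kind,
    substitution = paste0(x$ref_allele, ">", x$alt_allele),
    deletion     = paste0("del", x$ref_allele),
    duplication  = paste0("dup", x$ref_allele),
    insertion    = paste0("ins", x$alt_allele),
    delins       = paste0("delins", x$alt_allele)
  )
  paste0("c.", loc, edit)
}

#' Parse a protein HGVS string
#'
#' Recognizes missense (`p.Arg24His`), nonsense (`p.Trp1618Ter`), and
#' frameshift (`p.Gln1852ArgfsTer3`, `p.Leu234fs`) notation with
#' three-letter amino-acid codes; an enclosing parenthesis
#' (`p.(Arg24His)`) is tolerated.
#'
#' @param text A single HGVS string beginning with `"p."`.
#' @return An object of class `protein_change` with fields `ref_residue`,
#'   `residue_number`, `alt_residue`, `frameshift`, `fs_ter_distance`
#'   (`NA` when the new reading frame's stop distance is unknown).
#' @examples
#' parse_protein("p.Leu2230ProfsTer17")
#' @export
parse_protein <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  raw <- text
  text <- normalize_hgvs(text)
  if (!startsWith(text, "p.")) {
    parse_error("protein HGVS must begin with \"p.\"", raw)
  }
  body <- sub("^p\\.\\((.*)\\)$", "p.\\1", text)
  body <- substring(body, 3L)

  m <- regexec("^([A-Z][a-z]{2})(\\d+)(.*)$", body)
  parts <- regmatches(body, m)[[1]]
  if (length(parts) == 0L) {
    parse_error("could not read the reference residue", raw)
  }
  ref <- parts[[2]]
  num <- as.integer(parts[[3]])
  rest <- parts[[4]]
  if (!ref %in% AA3) parse_error(paste0("unknown residue code \"", ref, "\""), raw)
  if (num < 1L) parse_error("residue number must be >= 1", raw)

  frameshift <- FALSE
  fs_ter <- NA_integer_
  alt <- NULL
  if (grepl("^(Ter|[A-Z][a-z]{2})?fs(Ter(\\d+|\\?))?$", rest)) {
    frameshift <- TRUE
    alt <- sub("fs.*$", "", rest)
    if (alt == "") alt <- NA_character_
    ter <- regmatches(rest, regexec("fsTer(\\d+)$", rest))[[1]]
    if (length(ter) == 2L) fs_ter <- as.integer(ter[[2]])
  } else if (grepl("^(Ter|[A-Z][a-z]{2})$", rest)) {
    alt <- rest
  } else {
    parse_error(paste0("unsupported protein edit \"", rest, "\""), raw)
  }
  if (!is.na(alt) && !alt %in% AA3) {
    parse_error(paste0("unknown residue code \"", alt, "\""), raw)
  }

  structure(
    list(
      ref_residue = ref, residue_number = num,
      alt_residue = alt,
      frameshift = frameshift, fs_ter_distance = fs_ter
    ),
    class = "protein_change"
  )
}

#' Format a protein change back to HGVS notation
#' @param x A `protein_change`.
#' @return A single HGVS `"p."` string.
#' @export
format_protein <- function(x) {
  stopifnot(inherits(x, "protein_change"))
  tail <- if (x$frameshift) {
    paste0(
      if (!is.na(x$alt_residue)) x$alt_residue else "",
      "fs",
      if (!is.na(x$fs_ter_distance)) paste0("Ter", x$fs_ter_distance) else ""
    )
  } else {
    x$alt_residue
  }
  paste0("p.", x$ref_residue, x$residue_number, tail)
}

#' Parse a genomic CNV region
#'
#' Reads notation of the form `chr1:94480267-94482198del` (1-based,
#' inclusive).
#'
#' @param text A single region string.
#' @return An object of class `genomic_region` with `chromosome`,
#'   `start`, `end`, `operation`.
#' @export
parse_genomic_region <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  raw <- text
  text <- normalize_hgvs(text)
  m <- regexec("^(chr[0-9XYM]+|[0-9XYM]+):(\\d+)-(\\d+)del$", text)
  parts <- regmatches(text, m)[[1]]
  if (length(parts) == 0L) {
    parse_error("unsupported genomic region (expected chrN:start-enddel)", raw)
  }
  start <- as.integer(parts[[3]])
  end <- as.integer(parts[[4]])
  if (start > end) parse_error("region start exceeds end", raw)
  structure(
    list(chromosome = parts[[2]], start = start, end = end,
         operation = "deletion"),
    class = "genomic_region"
  )
}

#' Format a genomic region
#' @param x A `genomic_region`.
#' @return A single region string.
#' @export
format_genomic_region <- function(x) {
  stopifnot(inherits(x, "genomic_region"))
  sprintf("%s:%d-%ddel", x$chromosome, x$start, x$end)
}

#' Infer the consequence class of a variant
#'
#' Protein notation dominates when present: a frameshift token yields
#' `frameshift`; a `Ter` alternate without frameshift yields `nonsense`
#' (this covers deletions annotated with a direct stop, such as
#' `c.1378del (p.Val460Ter)`); an altered initiator residue yields
#' `start_loss`; two distinct residues yield `missense`. Without protein
#' annotation the intron offset decides: |offset| 1-2 is
#' `canonical_splice`, 3..`near_splice_window` is `near_splice_intronic`
#' (prediction-dependent), beyond the window is `deep_intronic`. Exonic
#' indels without protein annotation are `inframe_indel` when the
#' affected length is a multiple of 3, otherwise `frameshift`. A genomic
#' deletion is `cnv_deletion`.
#'
#' @param cdna A `cdna_change` or `NULL`.
#' @param protein A `protein_change` or `NULL`.
#' @param genomic A `genomic_region` or `NULL`.
#' @param near_splice_window Intronic offset (nt) up to which a variant
#'   is considered near-splice; default 20, must be >= 3.
#' @return One of `missense`, `nonsense`, `frameshift`, `inframe_indel`,
#'   `canonical_splice`, `near_splice_intronic`, `deep_intronic`,
#'   `cnv_deletion`, `start_loss`, `other`.
#' @examples
#' infer_consequence(cdna = parse_cdna("c.2919-1G>A"))
#' infer_consequence(protein = parse_protein("p.Trp1618Ter"))
#' @export
infer_consequence <- function(cdna = NULL, protein = NULL, genomic = NULL,
                              near_splice_window = 20L) {
  stopifnot(near_splice_window >= 3L)
  if (!is.null(protein)) {
    p <- protein
    if (p$frameshift) return("frameshift")
    if (identical(p$alt_residue, "Ter")) return("nonsense")
    if (p$residue_number == 1L && !identical(p$alt_residue, p$ref_residue)) {
      return("start_loss")
    }
    if (!is.na(p$alt_residue) && !identical(p$alt_residue, p$ref_residue)) {
      return("missense")
    }
    return("other")
  }
  if (!is.null(cdna)) {
    off <- abs(cdna$intron_offset)
    if (off >= 1L) {
      if (off <= 2L) return("canonical_splice")
      if (off <= near_splice_window) return("near_splice_intronic")
      return("deep_intronic")
    }
    if (cdna$edit_kind == "substitution") return("other")
    len <- edit_length(cdna)
    if (!is.na(len) && len %% 3L == 0L && cdna$edit_kind != "insertion") {
      return("inframe_indel")
    }
    if (cdna$edit_kind == "insertion" && !is.na(len) && len %% 3L == 0L) {
      return("inframe_indel")
    }
    return("frameshift")
  }
  if (!is.null(genomic)) return("cnv_deletion")
  rlang::abort("unclassifiable variant: no cDNA, protein, or genomic field",
               class = "abca4_unclassifiable_error")
}

# Length of sequence added or removed by an exonic indel, NA if unknown.
edit_length <- function(cdna) {
  switch(cdna$edit_kind,
    deletion = ,
    duplication = {
      if (!is.na(cdna$anchor_end)) {
        cdna$anchor_end - cdna$anchor_position + 1L
      } else if (nzchar(cdna$ref_allele)) {
        nchar(cdna$ref_allele)
      } else {
        1L
      }
    },
    insertion = ,
    delins = if (nzchar(cdna$alt_allele)) nchar(cdna$alt_allele) else NA_integer_,
    NA_integer_
  )
}

#' Build a variant descriptor from notation strings
#'
#' Parses whichever of the three notations are provided and infers the
#' consequence class. At least one of `cdna_hgvs` and `genomic_region`
#' must be non-empty.
#'
#' @param cdna_hgvs,protein_hgvs,genomic_region Notation strings; `""` or
#'   `NA` marks an absent field.
#' @param novel Logical novelty flag.
#' @param near_splice_window Passed to [infer_consequence()].
#' @return An object of class `variant_descriptor` with the parsed
#'   components, the `consequence`, `novel`, and a normalized `key`
#'   (cDNA string, or genomic string for CNVs) used for deduplication.
#' @export
variant_descriptor <- function(cdna_hgvs = NA, protein_hgvs = NA,
                               genomic_region = NA, novel = FALSE,
                               near_splice_window = 20L) {
  has <- function(x) length(x) == 1L && !is.na(x) && nzchar(trimws(x))
  cdna <- if (has(cdna_hgvs)) parse_cdna(cdna_hgvs) else NULL
  protein <- if (has(protein_hgvs)) parse_protein(protein_hgvs) else NULL
  genomic <- if (has(genomic_region)) parse_genomic_region(genomic_region) else NULL
  if (is.null(cdna) && is.null(genomic)) {
    rlang::abort("a variant needs a cDNA or genomic description",
                 class = "abca4_unclassifiable_error")
  }
  structure(
    list(
      cdna = cdna, protein = protein, genomic = genomic,
      novel = isTRUE(novel) || identical(novel, 1L) || identical(novel, 1),
      consequence = infer_consequence(cdna, protein, genomic,
                                      near_splice_window),
      key = if (!is.null(cdna)) format_cdna(cdna) else format_genomic_region(genomic)
    ),
    class = "variant_descriptor"
  )
}

#' @export
print.variant_descriptor <- function(x, ...) {
  cat("<variant> ", x$key,
      if (!is.null(x$protein)) paste0(" (", format_protein(x$protein), ")"),
      "  [", x$consequence, "]",
      if (x$novel) "  novel", "\n", sep = "")
  invisible(x)
}

#' @export
print.cdna_change <- function(x, ...) {
  cat("<cdna_change> ", format_cdna(x), "\n", sep = "")
  invisible(x)
}

#' @export
print.protein_change <- function(x, ...) {
  cat("<protein_change> ", format_protein(x), "\n", sep = "")
  invisible(x)
}
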