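# Coding-effect annotation in CDS space. Positions are 1-based nucleotides
# within the coding sequence of the transcript named in the variant
# definition; translation uses the standard genetic code (Biostrings).

#' Annotate the coding effect of a variant against a CDS
#'
#' For an SNV the affected codon and amino acids are computed directly:
#' codon number `ceiling(cds_pos / 3)`, within-codon position
#' `(cds_pos - 1) %% 3 + 1`. Deletions (alt `"-"`, or ref longer than alt
#' with a shared anchor base) are classified as `inframe_deletion` when the
#' deleted length is a multiple of three and `frameshift` otherwise.
#'
#' @param cds coding sequence: a character string or `Biostrings::DNAString`,
#'   length divisible by 3.
#' @param variant one-row variant definition (data.frame or list) with
#'   `cds_pos`, `ref`, `alt`.
#' @return list of class `coding_effect` with `codon_number`,
#'   `codon_position` (SNV only), `ref_codon`, `alt_codon`, `ref_aa`,
#'   `alt_aa`, `effect_class`, `substitution_class`.
#' @export
annotate_coding_effect <- function(cds, variant) {
  cds <- toupper(as.character(cds))
  if (nchar(cds) %% 3 != 0) stop_apobec3("CDS length must be divisible by 3")
  pos <- as.integer(variant$cds_pos)
  ref <- toupper(variant$ref)
  alt <- toupper(variant$alt)
  if (pos < 1 || pos > nchar(cds)) stop_apobec3("cds_pos outside the CDS")

  if (nchar(ref) == 1L && nchar(alt) == 1L && alt != "-") {
    found <- substr(cds, pos, pos)
    if (found != ref) {
      stop_apobec3(sprintf(
        "reference mismatch at CDS position %d: expected '%s', CDS has '%s'",
        pos, ref, found))
    }
    codon_number <- ceiling(pos / 3)
    codon_position <- (pos - 1L) %% 3L + 1L
    codon_start <- (codon_number - 1L) * 3L + 1L
    ref_codon <- substr(cds, codon_start, codon_start + 2L)
    alt_codon <- ref_codon
    substr(alt_codon, codon_position, codon_position) <- alt
    ref_aa <- translate_codon(ref_codon)
    alt_aa <- translate_codon(alt_codon)
    effect <- if (ref_aa == alt_aa) "synonymous" else "nonsynonymous"
    return(structure(list(
      codon_number = codon_number, codon_position = codon_position,
      ref_codon = ref_codon, alt_codon = alt_codon,
      ref_aa = ref_aa, alt_aa = alt_aa,
      effect_class = effect,
      substitution_class = substitution_class(ref, alt)
    ), class = "coding_effect"))
  }

  # deletion: alt "-" deletes the ref bases at pos; an anchored form
  # (ref = anchor + deleted, alt = anchor) is also accepted
  if (alt == "-") {
    deleted <- ref
    del_start <- pos
  } else if (nchar(ref) > nchar(alt) && startsWith(ref, alt)) {
    deleted <- substr(ref, nchar(alt) + 1L, nchar(ref))
    del_start <- pos + nchar(alt)
  } else {
    stop_apobec3("unsupported allele pair: ref '", ref, "', alt '", alt, "'")
  }
  found <- substr(cds, del_start, del_start + nchar(deleted) - 1L)
  if (found != deleted) {
    stop_apobec3(sprintf(
      "reference mismatch at CDS position %d: expected '%s', CDS has '%s'",
      del_start, deleted, found))
  }
  inframe <- nchar(deleted) %% 3L == 0L
  codon_number <- ceiling(del_start / 3)
  ref_aa <- if (inframe && (del_start - 1L) %% 3L == 0L) {
    translate_codon(deleted)  # whole-codon deletion
  } else {
    NA_character_
  }
  structure(list(
    codon_number = codon_number, codon_position = NA_integer_,
    ref_codon = NA_character_, alt_codon = NA_character_,
    ref_aa = ref_aa, alt_aa = "del",
    effect_class = if (inframe) "inframe_deletion" else "frameshift",
    substitution_class = "indel"
  ), class = "coding_effect")
}

#' @export
print.coding_effect <- function(x, ...) {
  if (!is.na(x$codon_position)) {
    cat(sprintf("codon %d pos %d: %s>%s (%s>%s), %s, %s\n",
                x$codon_number, x$codon_position, x$ref_codon, x$alt_codon,
                x$ref_aa, x$alt_aa, x$effect_class, x$substitution_class))
  } else {
    cat(sprintf("codon %d: deletion of %s, %s\n",
                x$codon_number, x$ref_aa %||% "?", x$effect_class))
  }
  invisible(x)
}

#' @noRd
translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[toupper(codon)]]
  if (is.null(aa)) stop_apobec3("cannot translate codon '", codon, "'")
  aa
}

# Codons that must sit at specific positions of each synthetic CDS so that
# the study variants annotate correctly; everything else is padded with a
# neutral alanine codon. These are fixture sequences, not the Ensembl
# transcripts (which are not redistributed); transcript IDs are metadata.
SYNTHETIC_CDS_SPEC <- list(
  ENST00000216099 = list(  # A3D, 386 aa
    n_aa = 386,
    codons = c("6" = "AGA", "97" = "CGC", "221" = "CTG", "224" = "TGT",
               "238" = "ACA", "248" = "AGG", "316" = "ACC", "320" = "TGC")
  ),
  ENST00000308521 = list(  # A3F isoform 201, 373 aa
    n_aa = 373,
    codons = c("48" = "CGT", "78" = "GCC", "87" = "ATC", "108" = "GCT",
               "117" = "ATC", "118" = "TCC", "143" = "CGC", "196" = "TAT",
               "229" = "TCA", "231" = "GTC", "245" = "GAG", "307" = "TAC",
               "327" = "TCC")
  ),
  ENST00000381565 = list(  # A3F isoform 202, 101 aa
    n_aa = 101,
    codons = c("87" = "CAG")
  ),
  ENST00000407997 = list(  # A3G, 384 aa
    n_aa = 384,
    codons = c("60" = "TCC", "109" = "GCC", "119" = "TTT", "186" = "CAC",
               "256" = "CGC", "275" = "CAG", "363" = "GGA", "371" = "CTG")
  ),
  ENST00000442487 = list(  # A3H, 183 aa
    n_aa = 183,
    codons = c("14" = "CAA", "15" = "AAC", "18" = "CGC", "43" = "ACG",
               "105" = "GGC", "121" = "AAG", "140" = "AAG", "178" = "GAG")
  )
)

#' Synthetic CDS fixture for a transcript
#'
#' Builds a short synthetic coding sequence carrying the exact codons of the
#' study variants at the correct codon numbers, padded elsewhere with a
#' neutral alanine codon (ATG start, TAA stop). These fixtures exist so the
#' annotator can be exercised without redistributing Ensembl transcripts.
#'
#' @param transcript_id one of the transcript identifiers in
#'   [apobec3_variants()], or a gene name (`A3D`, `A3F` selects isoform 201,
#'   `A3G`, `A3H`).
#' @return a `Biostrings::DNAString` of length `3 * (n_aa + 1)` (CDS
#'   including the stop codon).
#' @export
synthetic_cds <- function(transcript_id) {
  by_gene <- c(A3D = "ENST00000216099", A3F = "ENST00000308521",
               A3G = "ENST00000407997", A3H = "ENST00000442487")
  if (transcript_id %in% names(by_gene)) transcript_id <- by_gene[[transcript_id]]
  spec <- SYNTHETIC_CDS_SPEC[[transcript_id]]
  if (is.null(spec)) stop_apobec3("no synthetic CDS for '", transcript_id, "'")
  codons <- rep("GCT", spec$n_aa + 1L)
  codons[1L] <- "ATG"
  codons[spec$n_aa + 1L] <- "TAA"
  codons[as.integer(names(spec$codons))] <- unname(spec$codons)
  Biostrings::DNAString(paste(codons, collapse = ""))
}

#' Write the synthetic CDS fixtures to a FASTA file
#'
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_synthetic_cds_fasta <- function(path) {
  ids <- names(SYNTHETIC_CDS_SPEC)
  seqs <- Biostrings::DNAStringSet(lapply(ids, synthetic_cds))
  names(seqs) <- paste0(ids, " synthetic CDS fixture")
  Biostrings::writeXStringSet(seqs, filepath = path)
  invisible(path)
}

#' Annotate all variants of a definition table against the synthetic CDS set
#'
#' @param variant_defs variant definition table (default: the study loci).
#' @return `variant_defs` with annotation columns appended (`codon_number`,
#'   `ref_codon`, `alt_codon`, `ref_aa`, `alt_aa`, `effect_class`,
#'   `substitution_class`).
#' @export
annotate_variant_table <- function(variant_defs = apobec3_variants()) {
  ann <- lapply(seq_len(nrow(variant_defs)), function(i) {
    def <- variant_defs[i, ]
    eff <- annotate_coding_effect(synthetic_cds(def$transcript_id), def)
    data.frame(codon_number = eff$codon_number,
               ref_codon = eff$ref_codon %||% NA_character_,
               alt_codon = eff$alt_codon %||% NA_character_,
               ref_aa = eff$ref_aa, alt_aa = eff$alt_aa,
               effect_class = eff$effect_class,
               substitution_class = eff$substitution_class,
               stringsAsFactors = FALSE)
  })
  cbind(variant_defs, do.call(rbind, ann))
}
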