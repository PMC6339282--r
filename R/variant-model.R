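# Cohort genotypes are stored as an integer dosage matrix (samples x
# variants): 0 hom-ref, 1 het, 2 hom-alt, NA missing. Calls are unordered
# allele pairs; phase present in input (e.g. "|" separators in VCF) is
# deliberately discarded, so dosage is a lossless encoding for biallelic
# sites. Variants are keyed by their `label`, which must be unique within a
# cohort.

#' Construct a cohort genotype container
#'
#' @param samples character vector of sample identifiers (ordered).
#' @param variants data.frame of variant definitions with at least columns
#'   `gene`, `label`, `cds_pos`, `ref`, `alt` (see [apobec3_variants()]).
#' @param geno integer matrix `length(samples)` x `nrow(variants)` of allele
#'   dosages (0/1/2, `NA` = missing call).
#' @return object of class `cohort_genotypes`.
#' @export
cohort_genotypes <- function(samples, variants, geno) {
  samples <- as.character(samples)
  if (anyDuplicated(samples)) stop_apobec3("duplicate sample identifiers")
  if (anyDuplicated(variants$label)) {
    stop_apobec3("variant labels must be unique within a cohort")
  }
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (nrow(geno) != length(samples) || ncol(geno) != nrow(variants)) {
    stop_apobec3("genotype matrix dimensions do not match samples x variants")
  }
  bad <- !is.na(geno) & !(geno %in% 0:2)
  if (any(bad)) stop_apobec3("dosages must be 0, 1, 2 or NA")
  dimnames(geno) <- list(samples, variants$label)
  structure(
    list(samples = samples, variants = variants, geno = geno),
    class = "cohort_genotypes"
  )
}

#' @export
print.cohort_genotypes <- function(x, ...) {
  cat(sprintf(
    "<cohort_genotypes> %d samples x %d variants (%s)\n",
    length(x$samples), nrow(x$variants),
    paste(unique(x$variants$gene), collapse = ", ")
  ))
  miss <- mean(is.na(x$geno))
  cat(sprintf("  missing calls: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' Per-gene sample size (samples with at least one non-missing call)
#'
#' @param cohort a [cohort_genotypes()] object.
#' @return named integer vector over genes present in the cohort.
#' @export
gene_sample_sizes <- function(cohort) {
  genes <- unique(cohort$variants$gene)
  out <- vapply(genes, function(g) {
    cols <- cohort$variants$label[cohort$variants$gene == g]
    sum(rowSums(!is.na(cohort$geno[, cols, drop = FALSE])) > 0L)
  }, integer(1))
  names(out) <- genes
  out
}

#' Read a per-individual genotype table
#'
#' Parses a tab-separated genotype table (header required) with columns
#' `sample_id`, `gene`, `variant_id`, `allele1`, `allele2`. The variant is
#' matched against `variant_defs` by `variant_id` or, where the identifier is
#' not unique within a gene (novel variants share `"NI"`), by the amino-acid
#' `label`. Allele values must be the variant's declared ref or alt allele,
#' or `"."`; a `"." "."` pair is recorded as a missing call.
#'
#' @param path path to the TSV file.
#' @param variant_defs variant definition table (see [apobec3_variants()]).
#' @return a [cohort_genotypes()] object covering all variants in
#'   `variant_defs`; cells with no row in the file are missing.
#' @export
read_genotype_table <- function(path, variant_defs = apobec3_variants()) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  required <- c("sample_id", "gene", "variant_id", "allele1", "allele2")
  if (!all(required %in% names(tab))) {
    stop_apobec3("genotype table must have header columns: ",
                 paste(required, collapse = ", "))
  }
  samples <- unique(tab$sample_id)
  geno <- matrix(NA_integer_, nrow = length(samples), ncol = nrow(variant_defs),
                 dimnames = list(samples, variant_defs$label))
  if (nrow(tab) > 0) {
    for (i in seq_len(nrow(tab))) {
      row <- tab[i, ]
      hit <- which(variant_defs$gene == row$gene &
                     (variant_defs$variant_id == row$variant_id |
                        variant_defs$label == row$variant_id))
      if (length(hit) == 0L) {
        stop_apobec3(sprintf("line %d: unknown variant '%s' for gene %s",
                             i + 1L, row$variant_id, row$gene))
      }
      if (length(hit) > 1L) {
        stop_apobec3(sprintf(
          "line %d: variant id '%s' is ambiguous for gene %s; use the amino-acid label",
          i + 1L, row$variant_id, row$gene))
      }
      def <- variant_defs[hit, ]
      al <- c(row$allele1, row$allele2)
      if (all(al == ".")) {
        geno[row$sample_id, def$label] <- NA_integer_
        next
      }
      ok <- al %in% c(def$ref, def$alt)
      if (!all(ok)) {
        stop_apobec3(sprintf(
          "line %d: allele '%s' not in {%s, %s, .} for variant %s",
          i + 1L, al[!ok][1], def$ref, def$alt, def$label))
      }
      geno[row$sample_id, def$label] <- sum(al == def$alt)
    }
  }
  cohort_genotypes(samples, variant_defs, geno)
}

#' Read genotypes from a minimal biallelic VCF
#'
#' Accepts VCF 4.x with biallelic records and a GT field. The CHROM column is
#' interpreted as the gene, POS as the 1-based CDS position and ID as the
#' variant label (matching the convention of [write_cohort_vcf()]). Phased
#' (`|`) and unphased (`/`) separators are both accepted; phase is discarded.
#' Multi-allelic records are rejected with instructions to split them.
#'
#' @param path path to an (uncompressed) VCF file.
#' @return a [cohort_genotypes()] object.
#' @export
read_vcf_minimal <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) stop_apobec3("VCF contains no records")
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi)) {
    stop_apobec3("multi-allelic records not supported; split them first ",
                 "(e.g. 'bcftools norm -m-'): ",
                 paste(fix$ID[multi], collapse = ", "))
  }
  gt_raw <- v@gt
  if (is.null(gt_raw) || !any(grepl("GT", gt_raw[, "FORMAT"]))) {
    stop_apobec3("VCF records lack a GT FORMAT field")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt)
  parse_gt <- function(g) {
    if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_integer_)
    alleles <- strsplit(g, "[/|]")[[1]]
    if (any(alleles == ".")) return(NA_integer_)
    if (!all(alleles %in% c("0", "1"))) {
      stop_apobec3("unexpected GT allele index '", g, "' in biallelic VCF")
    }
    sum(alleles == "1")
  }
  geno <- matrix(
    vapply(seq_along(samples),
           function(j) vapply(gt[, j], parse_gt, integer(1)),
           integer(nrow(fix))),
    nrow = nrow(fix), ncol = length(samples)
  )
  variants <- data.frame(
    gene = fix$CHROM,
    label = fix$ID,
    variant_id = fix$ID,
    transcript_id = NA_character_,
    cds_pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    exon = NA_integer_,
    effect = NA_character_,
    novel = FALSE,
    stringsAsFactors = FALSE
  )
  cohort_genotypes(samples, variants, t(geno))
}

#' Tally genotype classes for one variant
#'
#' @param cohort a [cohort_genotypes()] object.
#' @param variant variant label (or a one-row variant definition).
#' @return classed integer vector `genotype_counts` with elements `n_rr`,
#'   `n_ra`, `n_aa`; missing calls are excluded.
#' @export
count_genotypes <- function(cohort, variant) {
  label <- if (is.data.frame(variant)) variant$label else variant
  if (!label %in% colnames(cohort$geno)) {
    stop_apobec3("variant '", label, "' not present in cohort")
  }
  d <- cohort$geno[, label]
  genotype_counts(sum(d == 0L, na.rm = TRUE),
                  sum(d == 1L, na.rm = TRUE),
                  sum(d == 2L, na.rm = TRUE))
}

#' Construct a genotype-count triple
#'
#' @param n_rr,n_ra,n_aa non-negative integer counts of hom-ref, het and
#'   hom-alt individuals.
#' @return classed integer vector `genotype_counts`.
#' @export
genotype_counts <- function(n_rr, n_ra, n_aa) {
  if (!(is_count(n_rr) && is_count(n_ra) && is_count(n_aa))) {
    stop_apobec3("genotype counts must be non-negative integers")
  }
  structure(c(n_rr = as.integer(n_rr), n_ra = as.integer(n_ra),
              n_aa = as.integer(n_aa)),
            class = "genotype_counts")
}

#' @export
print.genotype_counts <- function(x, ...) {
  cat(sprintf("genotype counts: %d hom-ref / %d het / %d hom-alt (n = %d)\n",
              x[["n_rr"]], x[["n_ra"]], x[["n_aa"]], sum(x)))
  invisible(x)
}
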