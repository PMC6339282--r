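# Per-variant population statistics: allele frequencies, minor-allele-
# frequency filtering and the Hardy-Weinberg chi-squared test (1 df, no
# continuity correction — the convention that reproduces the published test
# statistics). Internal values are kept at full precision; rounding happens
# only in report formatting.

#' Allele frequencies from genotype counts
#'
#' @param counts a [genotype_counts()] triple.
#' @return list of class `allele_frequencies`: `ref_count`, `alt_count`,
#'   `two_n`, `ref_pct`, `alt_pct`, `maf_pct` (percentages on the 0-100
#'   scale, unrounded).
#' @export
allele_frequencies <- function(counts) {
  n <- sum(counts)
  if (n == 0L) stop_apobec3("allele frequencies undefined for n = 0")
  ref_count <- 2L * counts[["n_rr"]] + counts[["n_ra"]]
  alt_count <- counts[["n_ra"]] + 2L * counts[["n_aa"]]
  two_n <- 2L * n
  ref_pct <- 100 * ref_count / two_n
  alt_pct <- 100 * alt_count / two_n
  structure(list(
    ref_count = ref_count, alt_count = alt_count, two_n = two_n,
    ref_pct = ref_pct, alt_pct = alt_pct,
    maf_pct = min(ref_pct, alt_pct)
  ), class = "allele_frequencies")
}

#' @export
print.allele_frequencies <- function(x, ...) {
  cat(sprintf("alleles: ref %d (%.1f%%) / alt %d (%.1f%%), 2n = %d, MAF %.1f%%\n",
              x$ref_count, round_half_up(x$ref_pct, 1),
              x$alt_count, round_half_up(x$alt_pct, 1),
              x$two_n, round_half_up(x$maf_pct, 1)))
  invisible(x)
}

#' Hardy-Weinberg chi-squared test
#'
#' Compares observed genotype counts with the equilibrium expectation
#' (p^2 n, 2pq n, q^2 n) using a chi-squared statistic at one degree of
#' freedom. No continuity correction is applied by default and expected
#' classes are used even when small (no pooling). Monomorphic variants are
#' flagged and return a statistic of 0 with p = 1.
#'
#' @param counts a [genotype_counts()] triple.
#' @param correct apply Yates' continuity correction (default `FALSE`).
#' @return list of class `hwe_result`: `expected` (named numeric triple),
#'   `chi2`, `p_value`, `df` (always 1), `monomorphic`.
#' @export
hwe_chisq <- function(counts, correct = FALSE) {
  n <- sum(counts)
  if (n == 0L) stop_apobec3("HWE test undefined for n = 0")
  freqs <- allele_frequencies(counts)
  p <- freqs$ref_count / freqs$two_n
  q <- 1 - p
  expected <- c(e_rr = p^2 * n, e_ra = 2 * p * q * n, e_aa = q^2 * n)
  if (p == 0 || q == 0) {
    return(structure(list(expected = expected, chi2 = 0, p_value = 1,
                          df = 1L, monomorphic = TRUE),
                     class = "hwe_result"))
  }
  observed <- as.numeric(counts)
  dev <- abs(observed - expected)
  if (correct) dev <- pmax(dev - 0.5, 0)
  chi2 <- sum(dev^2 / expected)
  structure(list(
    expected = expected, chi2 = chi2,
    p_value = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
    df = 1L, monomorphic = FALSE
  ), class = "hwe_result")
}

#' @export
print.hwe_result <- function(x, ...) {
  if (x$monomorphic) {
    cat("HWE: monomorphic (chi2 = 0, p = 1)\n")
  } else {
    cat(sprintf("HWE chi2 = %.3f (df 1), p = %.4g\n", x$chi2, x$p_value))
  }
  invisible(x)
}

#' Partition variants by minor allele frequency
#'
#' A variant is "major" iff its minor-allele frequency is at least
#' `threshold_pct`; variants with MAF strictly below the threshold are
#' excluded ("minor").
#'
#' @param variants data.frame with a `label` column.
#' @param counts_list list of [genotype_counts()] parallel to `variants`.
#' @param threshold_pct percentage threshold in (0, 50].
#' @return list with data.frames `major` and `minor`, each `variants` plus a
#'   `maf_pct` column.
#' @export
maf_filter <- function(variants, counts_list, threshold_pct = 5) {
  stopifnot(threshold_pct > 0, threshold_pct <= 50,
            nrow(variants) == length(counts_list))
  maf <- vapply(counts_list, function(cc) allele_frequencies(cc)$maf_pct,
                numeric(1))
  variants$maf_pct <- maf
  keep <- maf >= threshold_pct
  list(major = variants[keep, , drop = FALSE],
       minor = variants[!keep, , drop = FALSE])
}

#' Per-variant summary table: counts, frequencies and HWE
#'
#' The per-gene report corresponding to the published variant table: one row
#' per variant with genotype counts, allele frequencies, the HWE chi-squared
#' statistic and a deviation flag at `alpha`.
#'
#' @param cohort a [cohort_genotypes()] object.
#' @param alpha significance level for the HWE deviation flag.
#' @return data.frame with one row per variant.
#' @export
hwe_table <- function(cohort, alpha = 0.05) {
  rows <- lapply(seq_len(nrow(cohort$variants)), function(i) {
    def <- cohort$variants[i, ]
    cc <- count_genotypes(cohort, def$label)
    n <- sum(cc)
    if (n == 0L) {
      return(data.frame(
        gene = def$gene, label = def$label, variant_id = def$variant_id,
        n = 0L, n_rr = 0L, n_ra = 0L, n_aa = 0L,
        ref_pct = NA_real_, alt_pct = NA_real_, maf_pct = NA_real_,
        chi2 = NA_real_, p_value = NA_real_, monomorphic = NA,
        hwe_deviation = NA, stringsAsFactors = FALSE
      ))
    }
    fr <- allele_frequencies(cc)
    hw <- hwe_chisq(cc)
    data.frame(
      gene = def$gene, label = def$label, variant_id = def$variant_id,
      n = n, n_rr = cc[["n_rr"]], n_ra = cc[["n_ra"]], n_aa = cc[["n_aa"]],
      ref_pct = fr$ref_pct, alt_pct = fr$alt_pct, maf_pct = fr$maf_pct,
      chi2 = hw$chi2, p_value = hw$p_value, monomorphic = hw$monomorphic,
      hwe_deviation = !hw$monomorphic && hw$p_value < alpha,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
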