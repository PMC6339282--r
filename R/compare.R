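# Cross-population allele-frequency comparison. References published only as
# percentages and chromosome counts are converted back to integer allele
# counts; 1000 Genomes-sized references are compared with a two-sided
# Fisher's exact test and very large exome aggregates with a 1-df Pearson
# chi-squared test (cutoff 2n > 10000, which reproduces the published split).

#' Reconstruct integer allele counts from published percentages
#'
#' @param two_n chromosome count of the reference population.
#' @param alt_pct published alternate-allele percentage.
#' @return integer vector `c(ref_count, alt_count)` with
#'   `alt_count = round(alt_pct/100 * two_n)` (half away from zero).
#' @export
reconstruct_counts <- function(two_n, alt_pct) {
  stopifnot(two_n > 0, alt_pct >= 0, alt_pct <= 100)
  alt_count <- as.integer(round_half_up(alt_pct / 100 * two_n))
  if (alt_count < 0L || alt_count > two_n) {
    stop_apobec3("reconstructed count outside [0, 2n]")
  }
  c(ref_count = two_n - alt_count, alt_count = alt_count)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Point-probability ("sum of all tables as or less likely") two-sided
#' definition: p is the sum of hypergeometric point probabilities, over all
#' tables with the observed margins, that do not exceed the probability of
#' the observed table. Computed in log space via [stats::dhyper()], so large
#' margins are handled without enumeration overflow. Degenerate margins give
#' p = 1.
#'
#' @param a,b,c,d cell counts: rows are groups, columns are alleles
#'   (`[[a, b], [c, d]]`).
#' @return the two-sided p-value.
#' @export
fisher_exact_two_sided <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  m <- a + b          # row 1 total
  n <- c + d          # row 2 total
  k <- a + c          # column 1 total
  if (m == 0 || n == 0 || k == 0 || (b + d) == 0) return(1)
  support <- max(0, k - n):min(k, m)
  logp <- stats::dhyper(support, m, n, k, log = TRUE)
  log_obs <- stats::dhyper(a, m, n, k, log = TRUE)
  # relative tolerance guards against ties broken by floating-point noise
  p <- sum(exp(logp[logp <= log_obs + log(1 + 1e-7)]))
  min(p, 1)
}

#' Pearson chi-squared test for a 2x2 table
#'
#' 1-df Pearson statistic `N (ad - bc)^2 / (r1 r2 c1 c2)`; no continuity
#' correction by default. Intended for very large references where exact
#' enumeration is unnecessary.
#'
#' @param a,b,c,d cell counts.
#' @param correct apply Yates' continuity correction.
#' @return list with `chi2` and `p_value`.
#' @export
chi2_two_by_two <- function(a, b, c, d, correct = FALSE) {
  # double arithmetic: products like a*d overflow 32-bit integers for
  # exome-aggregate-sized references
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) {
    stop_apobec3("chi-squared undefined with a zero margin; use Fisher's exact test")
  }
  n <- r1 + r2
  dev <- abs(a * d - b * c)
  if (correct) dev <- max(0, dev - n / 2)
  chi2 <- n * dev^2 / (r1 * r2 * c1 * c2)
  list(chi2 = chi2, p_value = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Compare cohort allele counts against reference populations
#'
#' One comparison per reference population: the cohort's ref/alt allele
#' counts against counts reconstructed from the reference's published
#' percentages. The test is Fisher's exact for modest references and
#' chi-squared for very large ones (`two_n > chi2_cutoff`), unless
#' `method_rule` overrides. References without a published frequency
#' (`NA` percentages) are skipped with their reason recorded.
#'
#' @param counts cohort [genotype_counts()] for the variant.
#' @param refpops data.frame with columns `population`, `two_n`, `alt_pct`
#'   (optionally `ref_count`/`alt_count` to override reconstruction, and
#'   `missing_reason`).
#' @param method_rule optional named character vector population -> method
#'   (`"fisher"` or `"chi2"`).
#' @param alpha significance threshold for the `significant` flag.
#' @param chi2_cutoff reference 2n above which chi-squared is used.
#' @return data.frame with one row per population: the 2x2 table cells,
#'   method, p-value, significance flag, and `skipped`/`skip_reason`.
#' @export
compare_populations <- function(counts, refpops, method_rule = NULL,
                                alpha = 0.05, chi2_cutoff = 10000) {
  freqs <- allele_frequencies(counts)
  rows <- lapply(seq_len(nrow(refpops)), function(i) {
    pop <- refpops[i, ]
    base <- data.frame(
      population = pop$population,
      cohort_ref = freqs$ref_count, cohort_alt = freqs$alt_count,
      pop_ref = NA_integer_, pop_alt = NA_integer_,
      method = NA_character_, chi2 = NA_real_, p_value = NA_real_,
      significant = NA, skipped = FALSE, skip_reason = "",
      stringsAsFactors = FALSE
    )
    if (is.na(pop$alt_pct)) {
      base$skipped <- TRUE
      base$skip_reason <- if (!is.null(pop$missing_reason) &&
                              nzchar(pop$missing_reason)) pop$missing_reason else "NA"
      return(base)
    }
    if (!is.null(pop$alt_count) && !is.na(pop$alt_count)) {
      pc <- c(ref_count = pop$two_n - pop$alt_count, alt_count = pop$alt_count)
    } else {
      pc <- reconstruct_counts(pop$two_n, pop$alt_pct)
    }
    method <- if (!is.null(method_rule) && pop$population %in% names(method_rule)) {
      method_rule[[pop$population]]
    } else if (pop$two_n > chi2_cutoff) "chi2" else "fisher"
    # chi-squared is undefined with a zero margin (e.g. a variant fixed in
    # both cohort and reference); Fisher handles these degenerate tables
    if (method == "chi2" &&
        (freqs$ref_count + pc[["ref_count"]] == 0 ||
         freqs$alt_count + pc[["alt_count"]] == 0)) {
      method <- "fisher"
    }
    base$pop_ref <- pc[["ref_count"]]
    base$pop_alt <- pc[["alt_count"]]
    base$method <- method
    if (method == "fisher") {
      base$p_value <- fisher_exact_two_sided(freqs$ref_count, freqs$alt_count,
                                             pc[["ref_count"]], pc[["alt_count"]])
    } else {
      ct <- chi2_two_by_two(freqs$ref_count, freqs$alt_count,
                            pc[["ref_count"]], pc[["alt_count"]])
      base$chi2 <- ct$chi2
      base$p_value <- ct$p_value
    }
    base$significant <- base$p_value <= alpha
    base
  })
  do.call(rbind, rows)
}

#' Full population-comparison report for a cohort
#'
#' Runs [compare_populations()] for every variant with a published reference
#' row, mirroring the shape of the published comparison tables.
#'
#' @param cohort a [cohort_genotypes()] object.
#' @param reference long-format reference table (see
#'   [apobec3_reference_freqs()]).
#' @param alpha significance threshold.
#' @return data.frame with one row per variant x population.
#' @export
comparison_table <- function(cohort, reference = apobec3_reference_freqs(),
                             alpha = 0.05) {
  labels <- intersect(cohort$variants$label, unique(reference$label))
  rows <- lapply(labels, function(lab) {
    cc <- count_genotypes(cohort, lab)
    if (sum(cc) == 0L) return(NULL)
    ref <- reference[reference$label == lab, , drop = FALSE]
    res <- compare_populations(cc, ref, alpha = alpha)
    cbind(gene = ref$gene[1], label = lab, res, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
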