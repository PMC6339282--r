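# Synthetic cohorts and deterministic fixtures. Two reconstruction modes
# exist for the published cohort because the publication's per-variant
# genotype tallies and its per-sample haplotype categories are not mutually
# consistent for A3H (site-15 tallies implied by the category table are
# 38/47/38 of 133 against printed per-variant counts of 29/49/55):
#   * "genotype_counts" fixtures reproduce the per-variant genotype tallies
#     exactly (margin assembly; used for frequency and HWE work and for the
#     stability headline);
#   * "haplotype_categories" fixtures expand the printed per-sample category
#     rows verbatim (used for diplotype-assignment work).

#' Simulation configuration
#'
#' @param n_samples cohort size (default 192, the study's recruitment size).
#' @param hap_freqs named list per gene: named numeric vector of haplotype
#'   frequencies (names must match rows of the gene's haplotype table).
#'   Defaults are calibrated to the study cohort: label frequencies from the
#'   confirmed category tallies, with the A3H deletion-side total set to the
#'   published 59.8% deletion allele frequency.
#' @param inbreeding_f inbreeding coefficient in `[0, 1]`: probability that a
#'   sample's two haplotypes are identical by descent (0 = random mating /
#'   HWE; 1 = fully homozygous).
#' @param missing_gene_rate named per-gene probability that a sample fails
#'   sequencing for the whole gene. Defaults are the study's per-gene failure
#'   rates (24/38/27/59 of 192).
#' @param seed integer seed.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_samples = 192,
                              hap_freqs = default_hap_freqs(),
                              inbreeding_f = 0,
                              missing_gene_rate = default_missing_rates(),
                              seed = 1L) {
  stopifnot(n_samples >= 1, inbreeding_f >= 0, inbreeding_f <= 1)
  for (g in names(hap_freqs)) {
    f <- hap_freqs[[g]]
    if (any(f < 0) || abs(sum(f) - 1) > 1e-8) {
      stop_apobec3("haplotype frequencies for ", g, " must be >= 0 and sum to 1")
    }
  }
  if (any(missing_gene_rate < 0 | missing_gene_rate > 1)) {
    stop_apobec3("missing_gene_rate must be in [0, 1]")
  }
  structure(list(n_samples = as.integer(n_samples), hap_freqs = hap_freqs,
                 inbreeding_f = inbreeding_f,
                 missing_gene_rate = missing_gene_rate,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Default per-gene haplotype frequencies for the simulator
#'
#' A3D/A3F/A3G frequencies are the haplotype tallies over the study's
#' confirmed diplotype categories. For A3H the deletion-carrying side is
#' fixed at the published 59.8% deletion allele frequency (the confirmed
#' categories alone imply only 50%), split across haplotypes III/IV/X in
#' their confirmed-category proportions, with the remainder on stable
#' haplotype II.
#'
#' @return named list of named numeric vectors.
#' @export
default_hap_freqs <- function() {
  a3h_del <- 0.598
  del_split <- c(III = 43, IV = 19, X = 50)
  del_split <- del_split / sum(del_split)
  list(
    A3D = c(i = 231, ii = 20, iii = 10, iv = 29) / 290,
    A3F = c(i = 47, iii = 38, iv = 5, vi = 4) / 94,
    A3G = c(i = 84, ii = 83, iii = 28, iv = 9) / 204,
    A3H = c(II = 1 - a3h_del, a3h_del * del_split)
  )
}

#' Default per-gene whole-gene missingness rates
#'
#' The study obtained sequence for 168/154/165/133 of 192 subjects per gene.
#'
#' @return named numeric vector.
#' @export
default_missing_rates <- function() {
  n <- apobec3_gene_n()
  (192 - n) / 192
}

#' @noRd
hap_allele_matrix <- function(hap_table) {
  sites <- hap_table_sites(hap_table)
  m <- as.matrix(hap_table[, sites, drop = FALSE])
  rownames(m) <- hap_table$label
  m
}

#' Simulate a diploid cohort from haplotype frequencies
#'
#' Per sample and gene: with probability `missing_gene_rate` the whole gene
#' is missing; otherwise two haplotypes are drawn from the gene's frequency
#' vector — independently with probability `1 - F`, identical by descent
#' with probability `F` — and unphased genotypes are emitted at the gene's
#' haplotype sites. The drawn haplotype labels (the hidden truth) are
#' attached as attribute `"truth"`, never written into genotype exports.
#'
#' @param config a [simulation_config()].
#' @param hap_tables per-gene haplotype tables (defaults to the shipped
#'   configuration).
#' @return a [cohort_genotypes()] object with a `truth` attribute
#'   (data.frame sample/gene/hap1/hap2).
#' @export
simulate_cohort <- function(config, hap_tables = apobec3_haplotype_tables()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  genes <- names(config$hap_freqs)
  defs_all <- apobec3_variants()
  samples <- sprintf("SIM%04d", seq_len(config$n_samples))
  var_rows <- list()
  geno_cols <- list()
  truth <- list()
  for (g in genes) {
    tab <- hap_tables[[g]]
    if (is.null(tab)) stop_apobec3("no haplotype table for gene '", g, "'")
    freqs <- config$hap_freqs[[g]]
    if (!all(names(freqs) %in% tab$label)) {
      stop_apobec3("haplotype frequencies for ", g,
                   " name haplotypes missing from the table")
    }
    alleles <- hap_allele_matrix(tab)[names(freqs), , drop = FALSE]
    sites <- colnames(alleles)
    n <- config$n_samples
    h1 <- sample.int(length(freqs), n, replace = TRUE, prob = freqs)
    ibd <- stats::runif(n) < config$inbreeding_f
    h2 <- ifelse(ibd, h1, sample.int(length(freqs), n, replace = TRUE, prob = freqs))
    miss_rate <- if (g %in% names(config$missing_gene_rate)) {
      config$missing_gene_rate[[g]]
    } else 0
    missing <- stats::runif(n) < miss_rate
    dosage <- (alleles[h1, , drop = FALSE] == "alt") +
      (alleles[h2, , drop = FALSE] == "alt")
    storage.mode(dosage) <- "integer"
    dosage[missing, ] <- NA_integer_
    geno_cols[[g]] <- dosage
    defs_g <- defs_all[match(sites, defs_all$label), , drop = FALSE]
    if (anyNA(defs_g$label)) {
      # sites outside the study loci (custom tables): minimal definitions
      defs_g <- data.frame(gene = g, label = sites, variant_id = sites,
                           transcript_id = NA_character_,
                           cds_pos = seq_along(sites), ref = "A", alt = "G",
                           exon = NA_integer_, effect = "nonsynonymous",
                           novel = FALSE, stringsAsFactors = FALSE)
    }
    var_rows[[g]] <- defs_g
    truth[[g]] <- data.frame(sample = samples, gene = g,
                             hap1 = ifelse(missing, NA_character_,
                                           names(freqs)[h1]),
                             hap2 = ifelse(missing, NA_character_,
                                           names(freqs)[h2]),
                             stringsAsFactors = FALSE)
  }
  variants <- do.call(rbind, var_rows)
  geno <- do.call(cbind, geno_cols)
  cohort <- cohort_genotypes(samples, variants, geno)
  attr(cohort, "truth") <- do.call(rbind, truth)
  cohort
}

#' Simulate a two-locus genotype table with known disequilibrium
#'
#' Haplotypes are drawn from frequencies `(p_A p_B + D, p_A q_B - D,
#' q_A p_B - D, q_A q_B + D)` and paired at random into `n` diploid
#' genotypes.
#'
#' @param p_A,p_B reference-allele frequencies at the two loci.
#' @param D linkage disequilibrium coefficient; must keep all four haplotype
#'   frequencies non-negative.
#' @param n number of individuals.
#' @param seed integer seed.
#' @return 3x3 genotype table (see [two_locus_genotype_counts()]) with
#'   attribute `"true_haplotype_counts"` (named counts of the 2n drawn
#'   haplotypes) and `"true_freqs"`.
#' @export
simulate_two_locus <- function(p_A, p_B, D, n, seed = 1L) {
  q_A <- 1 - p_A
  q_B <- 1 - p_B
  f <- c(f_AB = p_A * p_B + D, f_Ab = p_A * q_B - D,
         f_aB = q_A * p_B - D, f_ab = q_A * q_B + D)
  if (any(f < -1e-12)) {
    lo <- -min(p_A * p_B, q_A * q_B)
    hi <- min(p_A * q_B, q_A * p_B)
    stop_apobec3(sprintf("inadmissible D = %g; admissible interval is [%g, %g]",
                         D, lo, hi))
  }
  f <- pmax(f, 0)
  set.seed(seed)
  haps <- sample.int(4L, 2L * n, replace = TRUE, prob = f)
  h1 <- haps[seq_len(n)]
  h2 <- haps[n + seq_len(n)]
  # haplotype 1=AB, 2=Ab, 3=aB, 4=ab; dosage of the a/b (alternate) allele
  da <- (h1 > 2) + (h2 > 2)
  db <- (h1 %% 2 == 0) + (h2 %% 2 == 0)
  tab <- table(factor(da, levels = 0:2), factor(db, levels = 0:2))
  out <- matrix(as.integer(tab), nrow = 3, dimnames = list(A = 0:2, B = 0:2))
  cnt <- tabulate(haps, nbins = 4L)
  names(cnt) <- names(f)
  attr(out, "true_haplotype_counts") <- cnt
  attr(out, "true_freqs") <- f
  out
}

# --- deterministic fixtures from the published tables -----------------------

#' @noRd
fixture_samples <- function(gene, n) sprintf("%s%03d", gene, seq_len(n))

#' Fixture cohort reproducing the published per-variant genotype tallies
#'
#' Deterministic margin assembly: for each variant, genotype classes are laid
#' onto the sample index range in a fixed order, so every per-variant tally
#' equals the published count table exactly. For A3H the layout places the
#' rare reference-allele carriers at sites 105/121/178 among deletion
#' heterozygotes, consistent with the study's observation that only
#' haplotypes II, III, IV and X segregate; the joint patterns of other genes
#' are arbitrary (only the margins are published).
#'
#' @param gene gene identifier.
#' @return a [cohort_genotypes()] object over the gene's study variants.
#' @export
fixture_cohort_from_counts <- function(gene) {
  counts <- apobec3_genotype_counts()
  counts <- counts[counts$gene == gene, , drop = FALSE]
  if (nrow(counts) == 0L) stop_apobec3("unknown gene '", gene, "'")
  defs <- apobec3_variants()
  defs <- defs[defs$gene == gene, , drop = FALSE]
  defs <- defs[match(counts$label, defs$label), , drop = FALSE]
  n <- sum(counts[1, c("n_rr", "n_ra", "n_aa")])
  geno <- matrix(NA_integer_, nrow = n, ncol = nrow(defs),
                 dimnames = list(NULL, defs$label))
  if (gene == "A3H") {
    layout <- a3h_count_layout()
    for (lab in names(layout)) geno[, lab] <- layout[[lab]]
  } else {
    for (i in seq_len(nrow(counts))) {
      cc <- counts[i, ]
      geno[, cc$label] <- rep(c(0L, 1L, 2L), c(cc$n_rr, cc$n_ra, cc$n_aa))
    }
  }
  cohort_genotypes(fixture_samples(gene, n), defs, geno)
}

# A3H joint layout over 133 samples satisfying the published per-variant
# tallies. Samples 1-29 are reference-homozygous at site 15, 30-78
# heterozygous, 79-133 deletion-homozygous; rare reference alleles at
# 105/121/178 and the synonymous 43 are placed so that every sample not
# homozygous for the deletion either carries stable haplotype II or has
# phase-ambiguous (unknown) stability.
#' @noRd
a3h_count_layout <- function() {
  lay <- function(pairs) {
    v <- rep(2L, 133)  # most A3H sites are alt-homozygous in this cohort
    for (p in pairs) v[p$at] <- p$dosage
    v
  }
  list(
    N15del = rep(c(0L, 1L, 2L), c(29, 49, 55)),
    R18L = {
      v <- rep(0L, 133); v[79:93] <- 1L; v[94:99] <- 2L; v
    },
    G105R = lay(list(list(at = 30, dosage = 0L), list(at = 31:34, dosage = 1L))),
    K121E = lay(list(list(at = 35, dosage = 0L), list(at = 36:41, dosage = 1L))),
    K140E = rep(2L, 133),
    E178D = lay(list(list(at = 100:102, dosage = 0L),
                     list(at = 103:113, dosage = 1L))),
    T43T = lay(list(list(at = 1:6, dosage = 0L), list(at = 7:13, dosage = 1L)))
  )
}

#' Fixture cohort expanding the published per-sample haplotype categories
#'
#' Each printed diplotype category row is expanded into `count` identical
#' samples with its multi-site genotype pattern at the gene's haplotype
#' sites. "Minor variant" and "Other" rows (whose per-sample detail is not
#' published) are reference-homozygous at the haplotype sites and carry one
#' designated excluded-site heterozygote. All other study variants are left
#' reference-homozygous.
#'
#' @param gene gene identifier.
#' @return a [cohort_genotypes()] object over the gene's study variants.
#' @export
fixture_cohort_from_categories <- function(gene) {
  cats <- apobec3_haplotype_categories()
  cats <- cats[cats$gene == gene, , drop = FALSE]
  if (nrow(cats) == 0L) stop_apobec3("unknown gene '", gene, "'")
  defs <- apobec3_variants()
  defs <- defs[defs$gene == gene, , drop = FALSE]
  sites <- hap_table_sites(apobec3_haplotype_tables()[[gene]])
  n <- sum(cats$count)
  geno <- matrix(0L, nrow = n, ncol = nrow(defs),
                 dimnames = list(NULL, defs$label))
  at <- 0L
  for (i in seq_len(nrow(cats))) {
    row <- cats[i, ]
    pattern <- as.integer(strsplit(row$pattern, ",")[[1]])
    stopifnot(length(pattern) == length(sites))
    idx <- at + seq_len(row$count)
    geno[idx, sites] <- matrix(pattern, nrow = row$count,
                               ncol = length(sites), byrow = TRUE)
    if (nzchar(row$carries)) geno[idx, row$carries] <- 1L
    at <- at + row$count
  }
  cohort_genotypes(fixture_samples(gene, n), defs, geno)
}

#' Deterministic fixture cohorts for all four genes
#'
#' @param source `"genotype_counts"` (margin assembly; per-variant tallies
#'   match the published count table exactly) or `"haplotype_categories"`
#'   (verbatim expansion of the published diplotype category rows). See the
#'   package vignette for why both exist.
#' @return named list of [cohort_genotypes()] objects (A3D, A3F, A3G, A3H).
#' @export
fixture_from_printed_tables <- function(source = c("genotype_counts",
                                                   "haplotype_categories")) {
  source <- match.arg(source)
  build <- switch(source,
                  genotype_counts = fixture_cohort_from_counts,
                  haplotype_categories = fixture_cohort_from_categories)
  out <- lapply(c(A3D = "A3D", A3F = "A3F", A3G = "A3G", A3H = "A3H"), build)
  expected_n <- apobec3_gene_n()
  for (g in names(out)) {
    if (length(out[[g]]$samples) != expected_n[[g]]) {
      stop_apobec3("fixture for ", g, " has wrong sample count")
    }
  }
  out
}

# --- writers ----------------------------------------------------------------

#' Write a cohort as a genotype TSV
#'
#' Long format: `sample_id`, `gene`, `variant_id`, `allele1`, `allele2` (one
#' row per sample x variant; missing calls written as `.`/`.`). Inverse of
#' [read_genotype_table()].
#'
#' @param cohort a [cohort_genotypes()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(cohort, path) {
  defs <- cohort$variants
  rows <- lapply(seq_len(nrow(defs)), function(j) {
    d <- cohort$geno[, defs$label[j]]
    a1 <- ifelse(is.na(d), ".", ifelse(d >= 1L, defs$alt[j], defs$ref[j]))
    a2 <- ifelse(is.na(d), ".", ifelse(d == 2L, defs$alt[j], defs$ref[j]))
    id <- if (defs$variant_id[j] == "NI") defs$label[j] else defs$variant_id[j]
    data.frame(sample_id = cohort$samples, gene = defs$gene[j],
               variant_id = id, allele1 = a1, allele2 = a2,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(match(tab$sample_id, cohort$samples)), , drop = FALSE]
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a cohort as a minimal biallelic VCF
#'
#' CHROM holds the gene, POS the CDS position, ID the variant label; the
#' deletion allele `"-"` is written as the IUPAC-free literal used in the
#' variant table. Inverse of [read_vcf_minimal()] up to phase (all calls are
#' written unphased).
#'
#' @param cohort a [cohort_genotypes()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort_vcf <- function(cohort, path) {
  defs <- cohort$variants
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", cohort$samples), collapse = "\t")
  ), con)
  for (j in seq_len(nrow(defs))) {
    d <- cohort$geno[, defs$label[j]]
    gt <- ifelse(is.na(d), "./.",
                 c("0/0", "0/1", "1/1")[d + 1L])
    writeLines(paste(c(defs$gene[j], defs$cds_pos[j], defs$label[j],
                       defs$ref[j], defs$alt[j], ".", "PASS", ".", "GT", gt),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Write the hidden simulation truth to a sidecar TSV
#'
#' @param cohort a [simulate_cohort()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_simulation_truth <- function(cohort, path) {
  truth <- attr(cohort, "truth")
  if (is.null(truth)) stop_apobec3("cohort carries no simulation truth")
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
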