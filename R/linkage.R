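# Pairwise linkage disequilibrium. LD statistics (D, D', R^2 and a 1-df
# goodness-of-fit chi-squared on chromosomes) are computed from two-locus
# haplotype frequencies; for unphased diploid genotypes the frequencies are
# first estimated by the standard EM over the double-heterozygote phase
# ambiguity. Allele "A"/"B" denotes the reference allele at each locus
# throughout; relabelling alleles leaves D' and R^2 unchanged.

#' Construct two-locus haplotype frequencies
#'
#' @param f_AB,f_Ab,f_aB,f_ab non-negative frequencies summing to 1.
#' @param source `"observed-phased"` or `"em-estimated"`.
#' @param converged for EM results, whether the tolerance was reached.
#' @return list of class `two_locus_haplotype_freqs`.
#' @export
two_locus_haplotype_freqs <- function(f_AB, f_Ab, f_aB, f_ab,
                                      source = "observed-phased",
                                      converged = TRUE) {
  f <- c(f_AB = unname(f_AB), f_Ab = unname(f_Ab),
         f_aB = unname(f_aB), f_ab = unname(f_ab))
  if (any(f < -1e-12)) stop_apobec3("haplotype frequencies must be >= 0")
  if (abs(sum(f) - 1) > 1e-9) stop_apobec3("haplotype frequencies must sum to 1")
  structure(list(f = pmax(f, 0), source = source, converged = converged),
            class = "two_locus_haplotype_freqs")
}

#' LD statistics from two-locus haplotype frequencies
#'
#' `D = f_AB - p_A p_B`; `Dmax` is the admissible extreme given the allele
#' frequencies (direction-dependent); `D' = |D| / Dmax`;
#' `R^2 = D^2 / (p_A q_A p_B q_B)`. The goodness-of-fit chi-squared is
#' `R^2 * n` on `n` chromosomes, at one degree of freedom.
#'
#' @param freqs a [two_locus_haplotype_freqs()] object.
#' @param n number of chromosomes behind the estimate.
#' @return list of class `ld_stats`: `D`, `D_prime`, `R2`, `chi2`, `p_value`,
#'   `n_chromosomes`, plus the allele frequencies `p_A`, `p_B`.
#' @export
ld_from_haplotypes <- function(freqs, n) {
  f <- freqs$f
  p_A <- f[["f_AB"]] + f[["f_Ab"]]
  p_B <- f[["f_AB"]] + f[["f_aB"]]
  q_A <- 1 - p_A
  q_B <- 1 - p_B
  if (p_A <= 0 || p_A >= 1 || p_B <= 0 || p_B >= 1) {
    stop_apobec3("LD undefined: monomorphic locus (allele frequency 0 or 1)")
  }
  D <- f[["f_AB"]] - p_A * p_B
  Dmax <- if (D > 0) min(p_A * q_B, q_A * p_B) else min(p_A * p_B, q_A * q_B)
  D_prime <- if (D == 0) 0 else abs(D) / Dmax
  R2 <- D^2 / (p_A * q_A * p_B * q_B)
  chi2 <- R2 * n
  structure(list(
    D = D, D_prime = D_prime, R2 = R2, chi2 = chi2,
    p_value = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
    n_chromosomes = n, p_A = p_A, p_B = p_B
  ), class = "ld_stats")
}

#' @export
print.ld_stats <- function(x, ...) {
  cat(sprintf("LD: D = %.4f, D' = %.3f, R2 = %.3f, chi2 = %.2f (p = %.3g, %d chrom)\n",
              x$D, x$D_prime, x$R2, x$chi2, x$p_value, x$n_chromosomes))
  invisible(x)
}

#' Two-locus genotype table from a cohort
#'
#' 3x3 table of genotype classes (rows: dosage at locus A; columns: dosage at
#' locus B), over samples with non-missing calls at both loci.
#'
#' @param cohort a [cohort_genotypes()] object.
#' @param label_a,label_b variant labels.
#' @return 3x3 integer matrix with dimnames 0/1/2.
#' @export
two_locus_genotype_counts <- function(cohort, label_a, label_b) {
  da <- cohort$geno[, label_a]
  db <- cohort$geno[, label_b]
  keep <- !is.na(da) & !is.na(db)
  tab <- table(factor(da[keep], levels = 0:2), factor(db[keep], levels = 0:2))
  m <- matrix(as.integer(tab), nrow = 3, dimnames = list(A = 0:2, B = 0:2))
  m
}

#' EM estimate of two-locus haplotype frequencies from unphased genotypes
#'
#' All genotype classes except the double heterozygote contribute known
#' gametes; the double heterozygote's two phase configurations are resolved
#' iteratively by the EM algorithm. The likelihood in the single free
#' parameter (the AB haplotype frequency; allele frequencies are fixed by
#' the margins) can be multimodal for small tables, so EM is run from three
#' deterministic starts — linkage-equilibrium products of the observed
#' allele frequencies plus the two phase-extreme (cis / trans) boundary
#' neighbourhoods — and the highest-likelihood solution is returned. When
#' the cis and trans starts tie in likelihood but disagree (the fully
#' phase-ambiguous case, e.g. a table of double heterozygotes only), the
#' equilibrium-start solution is returned, which resolves the symmetric
#' ambiguity at the D = 0 stationary point. The log-likelihood is
#' non-decreasing across iterations of each run.
#'
#' @param counts 3x3 genotype table (see [two_locus_genotype_counts()]).
#' @param tol convergence tolerance on the log-likelihood change.
#' @param max_iter maximum EM iterations per start; non-convergence is
#'   flagged on the result, not raised.
#' @return a [two_locus_haplotype_freqs()] with `source = "em-estimated"`,
#'   plus attributes `loglik` (trajectory of the returned run) and `n_iter`.
#' @export
em_haplotype_freqs <- function(counts, tol = 1e-8, max_iter = 1000) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == c(3, 3)), all(counts >= 0))
  n <- sum(counts)
  if (n == 0) stop_apobec3("empty genotype table")
  two_n <- 2 * n

  # fixed gamete contributions (dosage codes 0/1/2 = ref-hom/het/alt-hom;
  # haplotype order AB, Ab, aB, ab with A/B the reference alleles)
  base <- c(f_AB = 0, f_Ab = 0, f_aB = 0, f_ab = 0)
  base["f_AB"] <- 2 * counts[1, 1] + counts[1, 2] + counts[2, 1]
  base["f_Ab"] <- 2 * counts[1, 3] + counts[1, 2] + counts[2, 3]
  base["f_aB"] <- 2 * counts[3, 1] + counts[2, 1] + counts[3, 2]
  base["f_ab"] <- 2 * counts[3, 3] + counts[2, 3] + counts[3, 2]
  n_dh <- counts[2, 2]

  p_A <- (base[["f_AB"]] + base[["f_Ab"]] + n_dh) / two_n
  p_B <- (base[["f_AB"]] + base[["f_aB"]] + n_dh) / two_n

  loglik_of <- function(f) {
    probs <- c(
      f[["f_AB"]]^2, 2 * f[["f_AB"]] * f[["f_Ab"]], f[["f_Ab"]]^2,
      2 * f[["f_AB"]] * f[["f_aB"]],
      2 * (f[["f_AB"]] * f[["f_ab"]] + f[["f_Ab"]] * f[["f_aB"]]),
      2 * f[["f_Ab"]] * f[["f_ab"]],
      f[["f_aB"]]^2, 2 * f[["f_aB"]] * f[["f_ab"]], f[["f_ab"]]^2
    )
    obs <- c(counts[1, 1], counts[1, 2], counts[1, 3],
             counts[2, 1], counts[2, 2], counts[2, 3],
             counts[3, 1], counts[3, 2], counts[3, 3])
    sum(obs[obs > 0] * log(probs[obs > 0]))
  }

  run_em <- function(w_init) {
    # w_init: initial expected cis fraction of the double heterozygotes
    f <- (base + n_dh * c(w_init, 1 - w_init, 1 - w_init, w_init)) / two_n
    names(f) <- names(base)
    ll <- loglik_of(f)
    trajectory <- ll
    converged <- TRUE
    iter <- 0L
    if (n_dh > 0) {
      converged <- FALSE
      for (iter in seq_len(max_iter)) {
        cis <- f[["f_AB"]] * f[["f_ab"]]
        trans <- f[["f_Ab"]] * f[["f_aB"]]
        w_cis <- if (cis + trans > 0) cis / (cis + trans) else w_init
        f <- (base + n_dh * c(w_cis, 1 - w_cis, 1 - w_cis, w_cis)) / two_n
        names(f) <- names(base)
        ll_new <- loglik_of(f)
        trajectory <- c(trajectory, ll_new)
        if (abs(ll_new - ll) < tol) {
          ll <- ll_new
          converged <- TRUE
          break
        }
        ll <- ll_new
      }
    }
    list(f = f, loglik = ll, trajectory = trajectory,
         converged = converged, iter = iter)
  }

  if (n_dh > 0) {
    # equilibrium start: cis weight implied by independent allele frequencies
    indep <- c(p_A * p_B, p_A * (1 - p_B), (1 - p_A) * p_B,
               (1 - p_A) * (1 - p_B))
    w_eq <- {
      cis <- indep[1] * indep[4]; trans <- indep[2] * indep[3]
      if (cis + trans > 0) cis / (cis + trans) else 0.5
    }
    runs <- list(eq = run_em(w_eq), cis = run_em(0.999), trans = run_em(0.001))
    lls <- vapply(runs, `[[`, numeric(1), "loglik")
    best <- runs[[which.max(lls)]]
    tie <- abs(runs$cis$loglik - runs$trans$loglik) < 1e-9 &&
      max(abs(runs$cis$f - runs$trans$f)) > 1e-6
    if (tie && runs$eq$loglik <= max(lls)) best <- runs$eq
  } else {
    best <- run_em(0.5)
  }
  out <- two_locus_haplotype_freqs(best$f[["f_AB"]], best$f[["f_Ab"]],
                                   best$f[["f_aB"]], best$f[["f_ab"]],
                                   source = "em-estimated",
                                   converged = best$converged)
  attr(out, "loglik") <- best$trajectory
  attr(out, "n_iter") <- best$iter
  out
}

#' Pairwise LD matrix for a gene
#'
#' Computes LD statistics for every pair of polymorphic variants of a gene,
#' using EM-estimated haplotype frequencies over samples with calls at both
#' loci. The matrix is symmetric with unit diagonal.
#'
#' @param cohort a [cohort_genotypes()] object.
#' @param gene gene identifier.
#' @param stat which statistic to place in the matrix (`"R2"` or `"D_prime"`).
#' @return list with `matrix` (named square matrix of `stat`) and `pairs`
#'   (long data.frame: variant1, variant2, D, D_prime, R2, chi2, p_value,
#'   n_chrom).
#' @export
ld_matrix <- function(cohort, gene, stat = c("R2", "D_prime")) {
  stat <- match.arg(stat)
  labels <- cohort$variants$label[cohort$variants$gene == gene]
  poly <- vapply(labels, function(lab) {
    d <- cohort$geno[, lab]
    length(unique(stats::na.omit(d))) > 1L
  }, logical(1))
  labels <- labels[poly]
  if (length(labels) < 2L) {
    stop_apobec3("need >= 2 polymorphic variants in gene '", gene, "'")
  }
  k <- length(labels)
  m <- matrix(1, k, k, dimnames = list(labels, labels))
  pairs <- list()
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      tab <- two_locus_genotype_counts(cohort, labels[i], labels[j])
      n_chrom <- 2L * sum(tab)
      freqs <- em_haplotype_freqs(tab)
      ld <- ld_from_haplotypes(freqs, n_chrom)
      m[i, j] <- m[j, i] <- ld[[stat]]
      pairs[[length(pairs) + 1L]] <- data.frame(
        variant1 = labels[i], variant2 = labels[j],
        D = ld$D, D_prime = ld$D_prime, R2 = ld$R2,
        chi2 = ld$chi2, p_value = ld$p_value, n_chrom = n_chrom,
        em_converged = freqs$converged,
        stringsAsFactors = FALSE
      )
    }
  }
  list(matrix = m, pairs = do.call(rbind, pairs))
}
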