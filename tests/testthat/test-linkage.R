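test_that("LD statistics from haplotype frequencies handle the canonical cases", {
  indep <- two_locus_haplotype_freqs(0.25, 0.25, 0.25, 0.25)
  ld <- ld_from_haplotypes(indep, 100)
  expect_equal(ld$D, 0)
  expect_equal(ld$R2, 0)
  expect_equal(ld$D_prime, 0)
  expect_equal(ld$chi2, 0)

  coupled <- two_locus_haplotype_freqs(0.5, 0, 0, 0.5)
  ld2 <- ld_from_haplotypes(coupled, 200)
  expect_equal(ld2$D_prime, 1)
  expect_equal(ld2$R2, 1)
  expect_equal(ld2$chi2, 200)

  mono <- two_locus_haplotype_freqs(0.5, 0.5, 0, 0)
  expect_error(ld_from_haplotypes(mono, 100), "monomorphic")
})

test_that("R-squared equals the squared allele correlation (sampling oracle)", {
  set.seed(17)
  for (rep in 1:5) {
    repeat {
      f <- as.vector(stats::rmultinom(1, 60, rep(0.25, 4))) / 60
      p_A <- f[1] + f[2]; p_B <- f[1] + f[3]
      if (min(p_A, 1 - p_A, p_B, 1 - p_B) > 0.1) break
    }
    freqs <- two_locus_haplotype_freqs(f[1], f[2], f[3], f[4])
    ld <- ld_from_haplotypes(freqs, 1000)
    # sample indicator variables from the haplotype distribution
    n <- 2e5
    h <- sample.int(4, n, replace = TRUE, prob = f)
    xa <- as.integer(h <= 2)     # carries reference allele at locus A
    xb <- as.integer(h %% 2 == 1)  # carries reference allele at locus B
    expect_lt(abs(ld$R2 - stats::cor(xa, xb)^2), 1e-2)
  }
})

test_that("D-prime and R-squared are invariant under allele relabeling", {
  set.seed(31)
  for (rep in 1:20) {
    f <- as.vector(stats::rmultinom(1, 50, c(0.4, 0.2, 0.2, 0.2))) / 50
    if (any(c(f[1] + f[2], f[1] + f[3]) %in% c(0, 1))) next
    base <- ld_from_haplotypes(two_locus_haplotype_freqs(f[1], f[2], f[3], f[4]), 100)
    # swap alleles at locus A: AB<->aB, Ab<->ab
    swapA <- ld_from_haplotypes(two_locus_haplotype_freqs(f[3], f[4], f[1], f[2]), 100)
    # swap alleles at locus B: AB<->Ab, aB<->ab
    swapB <- ld_from_haplotypes(two_locus_haplotype_freqs(f[2], f[1], f[4], f[3]), 100)
    expect_equal(base$D_prime, swapA$D_prime, tolerance = 1e-12)
    expect_equal(base$R2, swapA$R2, tolerance = 1e-12)
    expect_equal(base$D_prime, swapB$D_prime, tolerance = 1e-12)
    expect_equal(base$R2, swapB$R2, tolerance = 1e-12)
  }
})

test_that("EM equals direct gamete counting when no double heterozygotes exist", {
  set.seed(23)
  for (rep in 1:10) {
    tab <- random_genotype_table(40)
    tab[2, 2] <- 0L
    if (sum(tab) == 0) next
    f <- em_haplotype_freqs(tab)
    two_n <- 2 * sum(tab)
    direct <- c(
      f_AB = 2 * tab[1, 1] + tab[1, 2] + tab[2, 1],
      f_Ab = 2 * tab[1, 3] + tab[1, 2] + tab[2, 3],
      f_aB = 2 * tab[3, 1] + tab[2, 1] + tab[3, 2],
      f_ab = 2 * tab[3, 3] + tab[2, 3] + tab[3, 2]
    ) / two_n
    expect_equal(f$f, direct, tolerance = 1e-12)
    expect_true(f$converged)
  }
})

test_that("the all-double-heterozygote table stays at the symmetric stationary point", {
  tab <- matrix(0L, 3, 3); tab[2, 2] <- 10L
  f <- em_haplotype_freqs(tab)
  expect_equal(unname(f$f), rep(0.25, 4), tolerance = 1e-9)
})

test_that("EM attains the grid-search likelihood maximum on small tables", {
  set.seed(47)
  n_checked <- 0L
  for (total in 2:8) {
    for (rep in 1:40) {
      tab <- random_genotype_table(total)
      # skip phase-direction-symmetric tables: no information on the sign
      # of D, resolved at the D = 0 stationary point by convention
      if (tab[2, 2] > 0 &&
          (identical(unname(tab[, 3:1]), unname(tab)) ||
           identical(unname(tab[3:1, ]), unname(tab)))) next
      em <- em_haplotype_freqs(tab, tol = 1e-12)
      grid <- oracle_em_grid(tab, step = 1e-3)
      ll_em <- {
        f <- em$f
        probs <- c(f[1]^2, 2 * f[1] * f[2], f[2]^2,
                   2 * f[1] * f[3], 2 * (f[1] * f[4] + f[2] * f[3]),
                   2 * f[2] * f[4], f[3]^2, 2 * f[3] * f[4], f[4]^2)
        obs <- as.vector(t(tab))
        sum(obs[obs > 0] * log(probs[obs > 0]))
      }
      expect_gte(ll_em, grid$loglik - 1e-6)
      n_checked <- n_checked + 1L
    }
  }
  expect_gte(n_checked, 200L)
})

test_that("EM log-likelihood is non-decreasing at every iteration", {
  set.seed(5)
  for (rep in 1:20) {
    tab <- simulate_two_locus(runif(1, 0.2, 0.8), runif(1, 0.2, 0.8), 0.03,
                              n = 200, seed = rep)
    ll <- attr(em_haplotype_freqs(tab), "loglik")
    expect_true(all(diff(ll) >= -1e-9))
  }
})

test_that("EM-estimated R2 tracks the true-phase R2 on synthetic cohorts", {
  set.seed(2024)
  diffs <- replicate(100, {
    p_A <- runif(1, 0.1, 0.9)
    p_B <- runif(1, 0.1, 0.9)
    dmax <- min(p_A * (1 - p_B), (1 - p_A) * p_B)
    dmin <- -min(p_A * p_B, (1 - p_A) * (1 - p_B))
    D <- runif(1, 0.5 * dmin, 0.5 * dmax)
    seed <- sample.int(1e6, 1)
    tab <- simulate_two_locus(p_A, p_B, D, n = 500, seed = seed)
    truth <- attr(tab, "true_haplotype_counts") / (2 * sum(tab))
    maf_ok <- min(truth[1] + truth[2], 1 - truth[1] - truth[2],
                  truth[1] + truth[3], 1 - truth[1] - truth[3]) >= 0.1
    if (!maf_ok) return(NA_real_)
    r2_true <- ld_from_haplotypes(
      two_locus_haplotype_freqs(truth[1], truth[2], truth[3], truth[4]),
      2 * sum(tab))$R2
    r2_em <- ld_from_haplotypes(em_haplotype_freqs(tab), 2 * sum(tab))$R2
    abs(r2_true - r2_em)
  })
  # the bulk of replicates agree tightly; under strong LD the loss of phase
  # information lets the EM estimate drift upward by a few hundredths, so
  # the tail is bounded rather than pinned
  diffs <- stats::na.omit(diffs)
  expect_gte(mean(diffs <= 0.02), 0.9)
  expect_lt(max(diffs), 0.1)
  expect_gte(length(diffs), 50)
})

test_that("the pairwise LD matrix is symmetric with unit diagonal and detects coupling", {
  # two perfectly correlated variants plus one independent
  set.seed(8)
  n <- 300
  d1 <- rbinom(n, 2, 0.4)
  d3 <- rbinom(n, 2, 0.3)
  defs <- data.frame(gene = "SIM", label = c("V1", "V2", "V3"),
                     variant_id = c("V1", "V2", "V3"),
                     transcript_id = NA, cds_pos = 1:3, ref = "A", alt = "G",
                     exon = NA, effect = "nonsynonymous", novel = FALSE)
  cohort <- cohort_genotypes(sprintf("S%03d", 1:n), defs, cbind(d1, d1, d3))
  ld <- ld_matrix(cohort, "SIM")
  expect_true(isSymmetric(ld$matrix))
  expect_equal(unname(diag(ld$matrix)), rep(1, 3))
  expect_equal(ld$matrix["V1", "V2"], 1, tolerance = 1e-9)
  pair12 <- ld$pairs[ld$pairs$variant1 == "V1" & ld$pairs$variant2 == "V2", ]
  expect_equal(pair12$D_prime, 1, tolerance = 1e-9)
  expect_equal(pair12$n_chrom, 2L * n)
})

test_that("independent variants show mean off-diagonal R2 near 1/chromosomes", {
  set.seed(12)
  n <- 400
  k <- 12
  geno <- sapply(1:k, function(i) rbinom(n, 2, 0.3))
  defs <- data.frame(gene = "SIM", label = paste0("V", 1:k),
                     variant_id = paste0("V", 1:k),
                     transcript_id = NA, cds_pos = 1:k, ref = "A", alt = "G",
                     exon = NA, effect = "nonsynonymous", novel = FALSE)
  cohort <- cohort_genotypes(sprintf("S%03d", 1:n), defs, geno)
  ld <- ld_matrix(cohort, "SIM")
  mean_r2 <- mean(ld$pairs$R2)
  expect_gt(mean_r2, 0.4 / (2 * n))
  expect_lt(mean_r2, 2.5 / (2 * n))
})
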