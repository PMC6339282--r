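# Independent oracles used against the package implementations. These stay
# deliberately naive (loops, direct enumeration, closed forms) and never call
# the code paths they check.

# Two-sided Fisher p by direct hypergeometric enumeration with log-factorial
# point probabilities (independent of stats::dhyper).
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  if (m == 0 || n == 0 || k == 0 || (b + d) == 0) return(1)
  support <- max(0, k - n):min(k, m)
  logp <- lgamma(m + 1) - lgamma(support + 1) - lgamma(m - support + 1) +
    lgamma(n + 1) - lgamma(k - support + 1) - lgamma(n - k + support + 1) -
    (lgamma(m + n + 1) - lgamma(k + 1) - lgamma(m + n - k + 1))
  obs <- logp[support == a]
  min(1, sum(exp(logp[logp <= obs + log(1 + 1e-7)])))
}

# HWE chi-squared via the allele-count parameterization
# chi2 = n * (n_ra^2 - 4 n_rr n_aa)^2 / ((2 n_rr + n_ra)^2 (2 n_aa + n_ra)^2)
# (algebraically equal to the observed-vs-expected three-class sum).
oracle_hwe_chi2 <- function(n_rr, n_ra, n_aa) {
  n <- n_rr + n_ra + n_aa
  r <- 2 * n_rr + n_ra
  a <- 2 * n_aa + n_ra
  if (r == 0 || a == 0) return(0)
  n * (n_ra^2 - 4 * n_rr * n_aa)^2 / (r^2 * a^2)
}

# Grid maximization of the two-locus genotype likelihood over f_AB (allele
# frequencies are margin-determined), at the given resolution.
oracle_em_grid <- function(counts, step = 1e-3) {
  counts <- as.matrix(counts)
  n <- sum(counts)
  two_n <- 2 * n
  # reference-allele frequencies from the margins (dosage 0 = ref-hom)
  p_A <- sum(rowSums(counts) * c(2, 1, 0)) / two_n
  p_B <- sum(colSums(counts) * c(2, 1, 0)) / two_n
  lo <- max(0, p_A + p_B - 1)
  hi <- min(p_A, p_B)
  if (lo > hi) lo <- hi  # guards float noise when the interval is a point
  grid <- seq(lo, hi, by = step)
  if (length(grid) == 0 || grid[length(grid)] < hi) grid <- c(grid, hi)
  ll <- vapply(grid, function(fab) {
    f <- c(fab, p_A - fab, p_B - fab, 1 - p_A - p_B + fab)
    f <- pmax(f, 0)
    probs <- c(f[1]^2, 2 * f[1] * f[2], f[2]^2,
               2 * f[1] * f[3], 2 * (f[1] * f[4] + f[2] * f[3]),
               2 * f[2] * f[4],
               f[3]^2, 2 * f[3] * f[4], f[4]^2)
    obs <- as.vector(t(counts))
    if (any(obs > 0 & probs <= 0)) return(-Inf)
    sum(obs[obs > 0] * log(probs[obs > 0]))
  }, numeric(1))
  list(f_AB = grid[which.max(ll)], loglik = max(ll), p_A = p_A, p_B = p_B)
}

# Draw a random 3x3 genotype table with a given total (uniform multinomial
# over cells).
random_genotype_table <- function(total) {
  cells <- as.vector(stats::rmultinom(1, total, rep(1 / 9, 9)))
  matrix(as.integer(cells), 3, 3, byrow = TRUE, dimnames = list(A = 0:2, B = 0:2))
}

# Random haplotype table over k sites with h distinct haplotypes.
random_hap_table <- function(k, h) {
  repeat {
    pats <- unique(replicate(h, sample(c("ref", "alt"), k, replace = TRUE),
                             simplify = FALSE))
    if (length(pats) == h) break
  }
  rows <- lapply(seq_along(pats), function(i) {
    as.data.frame(c(list(label = paste0("H", i)),
                    stats::setNames(as.list(pats[[i]]), paste0("S", seq_len(k))),
                    list(stability = "unknown")),
                  stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
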