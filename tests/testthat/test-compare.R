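test_that("reference allele counts reconstruct from published percentages", {
  # 0.034 * 1322 = 44.95 rounds (half away from zero) to 45
  expect_equal(unname(reconstruct_counts(1322, 3.4)), c(1277L, 45L))
  expect_equal(unname(reconstruct_counts(500, 0)), c(500L, 0L))
  expect_equal(unname(reconstruct_counts(500, 100)), c(0L, 500L))
})

test_that("two-sided Fisher p matches hand enumeration on tiny tables", {
  expect_equal(fisher_exact_two_sided(1, 1, 1, 1), 1)
  # [[3,0],[0,3]]: 4 tables with margins (3,3,3); extremes have prob 1/20
  expect_equal(fisher_exact_two_sided(3, 0, 0, 3), 0.1)
  expect_equal(fisher_exact_two_sided(0, 3, 3, 0), 0.1)
  # degenerate margins
  expect_equal(fisher_exact_two_sided(0, 0, 2, 3), 1)
  expect_equal(fisher_exact_two_sided(2, 0, 3, 0), 1)
})

test_that("Fisher p is invariant under transposition and row/column swaps", {
  set.seed(13)
  for (rep in 1:40) {
    t <- sample(0:25, 4, replace = TRUE)
    p <- fisher_exact_two_sided(t[1], t[2], t[3], t[4])
    expect_gte(p, 0)
    expect_lte(p, 1)
    expect_equal(p, fisher_exact_two_sided(t[1], t[3], t[2], t[4]),
                 tolerance = 1e-12)  # transpose
    expect_equal(p, fisher_exact_two_sided(t[4], t[3], t[2], t[1]),
                 tolerance = 1e-12)  # simultaneous row+column swap
    # p is at least the point probability of the observed table
    m <- t[1] + t[2]; n <- t[3] + t[4]; k <- t[1] + t[3]
    if (m > 0 && n > 0 && k > 0 && (t[2] + t[4]) > 0) {
      expect_gte(p, stats::dhyper(t[1], m, n, k) * (1 - 1e-9))
    }
  }
})

test_that("Fisher p agrees with stats::fisher.test as an independent route", {
  set.seed(99)
  for (rep in 1:30) {
    t <- sample(0:40, 4, replace = TRUE)
    if ((t[1] + t[2]) == 0 || (t[3] + t[4]) == 0 ||
        (t[1] + t[3]) == 0 || (t[2] + t[4]) == 0) next
    ours <- fisher_exact_two_sided(t[1], t[2], t[3], t[4])
    ref <- stats::fisher.test(matrix(t, 2, byrow = TRUE))$p.value
    expect_equal(ours, ref, tolerance = 1e-6)
  }
})

test_that("2x2 chi-squared matches the cell-by-cell expected-count identity", {
  res <- chi2_two_by_two(50, 50, 50, 50)
  expect_equal(res$chi2, 0)
  expect_equal(res$p_value, 1)
  expect_equal(chi2_two_by_two(10, 0, 0, 10)$chi2, 20)
  set.seed(21)
  for (rep in 1:30) {
    t <- sample(1:60, 4, replace = TRUE)
    got <- chi2_two_by_two(t[1], t[2], t[3], t[4])$chi2
    exp_cells <- outer(c(t[1] + t[2], t[3] + t[4]),
                       c(t[1] + t[3], t[2] + t[4])) / sum(t)
    obs <- matrix(t, 2, byrow = TRUE)
    expect_equal(got, sum((obs - exp_cells)^2 / exp_cells), tolerance = 1e-10)
  }
  expect_error(chi2_two_by_two(0, 0, 5, 5), "zero margin")
})

test_that("Fisher and chi-squared p agree on balanced large tables", {
  # balanced: both rows drawn from the same allele proportion. At the
  # reference scale where the package switches to chi-squared (margins in
  # the thousands), every non-tail table agrees within 10% relative; at
  # cohort scale the tests still track each other in the median, though
  # discreteness makes individual tables deviate more.
  set.seed(3)
  checked <- 0L
  for (rep in 1:40) {
    p <- runif(1, 0.3, 0.7)
    n1 <- sample(3000:20000, 1); n2 <- sample(3000:20000, 1)
    a <- rbinom(1, n1, p); c <- rbinom(1, n2, p)
    pf <- fisher_exact_two_sided(a, n1 - a, c, n2 - c)
    pc <- chi2_two_by_two(a, n1 - a, c, n2 - c)$p_value
    if (pf < 0.05) next
    checked <- checked + 1L
    expect_lt(abs(pf - pc) / max(pf, pc), 0.1)
  }
  expect_gte(checked, 20L)

  set.seed(4)
  rels <- vapply(1:100, function(rep) {
    p <- runif(1, 0.3, 0.7)
    n1 <- sample(150:400, 1); n2 <- sample(150:400, 1)
    a <- rbinom(1, n1, p); c <- rbinom(1, n2, p)
    t <- c(a, n1 - a, c, n2 - c)
    if (any(t < 20)) return(NA_real_)
    pf <- fisher_exact_two_sided(t[1], t[2], t[3], t[4])
    pc <- chi2_two_by_two(t[1], t[2], t[3], t[4])$p_value
    abs(pf - pc) / max(pf, pc)
  }, numeric(1))
  expect_lt(stats::median(rels, na.rm = TRUE), 0.1)
})

test_that("population comparison applies the method split and skips missing references", {
  refs <- apobec3_reference_freqs()
  t238a <- refs[refs$label == "T238A", ]
  res <- compare_populations(genotype_counts(154, 14, 0), t238a)
  expect_equal(nrow(res), 6L)
  expect_equal(res$method[res$population == "ExAC"], "chi2")
  expect_true(all(res$method[res$population != "ExAC"] == "fisher"))
  # all five superpopulation comparisons are highly significant
  sup <- res[res$population != "ExAC", ]
  expect_true(all(sup$p_value < 1e-4))
  expect_true(all(sup$significant))
  # row sums equal the respective chromosome counts
  expect_true(all(sup$cohort_ref + sup$cohort_alt == 336L))
  expect_equal(sup$pop_ref + sup$pop_alt, unname(sup$pop_ref + sup$pop_alt))

  # identical frequencies give p = 1 under Fisher
  same <- data.frame(population = "P", two_n = 336, ref_pct = NA, alt_pct = 11.0,
                     missing_reason = "")
  same$alt_pct <- 100 * 37 / 336
  res2 <- compare_populations(genotype_counts(133, 33, 2), same)
  expect_equal(res2$p_value, 1)

  # NI rows are skipped with the reason recorded
  r6k <- refs[refs$label == "R6K", ]
  res3 <- compare_populations(genotype_counts(151, 17, 0), r6k)
  expect_true(all(res3$skipped))
  expect_true(all(res3$skip_reason == "NI"))
})
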