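test_that("genotype TSV parsing handles valid rows, missing calls and empty files", {
  defs <- apobec3_variants()
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "sample_id\tgene\tvariant_id\tallele1\tallele2",
    "S001\tA3D\trs61748819\tG\tA",
    "S001\tA3D\trs75858538\tC\tC",
    "S002\tA3D\trs61748819\t.\t."
  ), path)
  cohort <- read_genotype_table(path, defs)
  expect_equal(cohort$samples, c("S001", "S002"))
  expect_equal(unname(cohort$geno["S001", "R248K"]), 1L)
  expect_equal(unname(cohort$geno["S001", "R97C"]), 0L)
  expect_true(is.na(cohort$geno["S002", "R248K"]))

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("sample_id\tgene\tvariant_id\tallele1\tallele2", empty)
  expect_length(read_genotype_table(empty, defs)$samples, 0L)
})

test_that("genotype TSV parsing rejects unknown variants and bad alleles with line numbers", {
  defs <- apobec3_variants()
  bad_var <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tgene\tvariant_id\tallele1\tallele2",
               "S001\tA3D\trs000\tG\tA"), bad_var)
  expect_error(read_genotype_table(bad_var, defs), "line 2.*unknown variant")

  bad_allele <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tgene\tvariant_id\tallele1\tallele2",
               "S001\tA3D\trs61748819\tG\tT"), bad_allele)
  expect_error(read_genotype_table(bad_allele, defs), "line 2.*allele 'T'")
})

test_that("minimal VCF ingest parses GT, treats ./. as missing and rejects multi-allelics", {
  fx <- fixture_cohort_from_counts("A3G")
  path <- withr::local_tempfile(fileext = ".vcf")
  write_cohort_vcf(fx, path)
  back <- read_vcf_minimal(path)
  expect_equal(back$samples, fx$samples)
  expect_equal(colnames(back$geno), colnames(fx$geno))
  expect_identical(unname(back$geno), unname(fx$geno))

  multi <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    "A3D\t289\trsX\tC\tT,G\t.\tPASS\t.\tGT\t0/1"
  ), multi)
  expect_error(read_vcf_minimal(multi), "multi-allelic")

  phased <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3",
    "A3D\t289\trsX\tC\tT\t.\tPASS\t.\tGT\t0|1\t1/1\t./."
  ), phased)
  cohort <- read_vcf_minimal(phased)
  expect_equal(unname(cohort$geno[, "rsX"]), c(1L, 2L, NA_integer_))
})

test_that("genotype tallies match a brute-force per-sample loop on simulated cohorts", {
  cfg <- simulation_config(n_samples = 120, seed = 11)
  cohort <- simulate_cohort(cfg)
  for (lab in c("R97C", "A108S", "N15del", "H186R")) {
    cc <- count_genotypes(cohort, lab)
    manual <- c(0L, 0L, 0L)
    for (s in cohort$samples) {
      d <- cohort$geno[s, lab]
      if (!is.na(d)) manual[d + 1L] <- manual[d + 1L] + 1L
    }
    expect_equal(unname(unclass(cc)), manual)
    expect_equal(sum(cc), sum(!is.na(cohort$geno[, lab])))
  }
  expect_error(count_genotypes(cohort, "nope"), "not present")
})

test_that("fixture cohorts reproduce the published genotype tallies", {
  gc <- apobec3_genotype_counts()
  fx <- fixture_from_printed_tables("genotype_counts")
  for (g in names(fx)) {
    sub <- gc[gc$gene == g, ]
    for (i in seq_len(nrow(sub))) {
      cc <- count_genotypes(fx[[g]], sub$label[i])
      expect_equal(unname(unclass(cc)),
                   c(sub$n_rr[i], sub$n_ra[i], sub$n_aa[i]),
                   info = paste(g, sub$label[i]))
    }
  }
  expect_equal(unname(unclass(count_genotypes(fx$A3D, "R248K"))), c(133L, 33L, 2L))
  expect_equal(unname(unclass(count_genotypes(fx$A3G, "H186R"))), c(63L, 82L, 20L))
})

test_that("coding-effect annotation reproduces the published codon changes", {
  v <- apobec3_variants()
  a3d <- synthetic_cds("A3D")
  r97c <- annotate_coding_effect(a3d, v[v$label == "R97C", ])
  expect_equal(r97c$codon_number, 97)
  expect_equal(r97c$codon_position, 1L)
  expect_equal(r97c$ref_codon, "CGC")
  expect_equal(r97c$alt_codon, "TGC")
  expect_equal(c(r97c$ref_aa, r97c$alt_aa), c("R", "C"))
  expect_equal(r97c$effect_class, "nonsynonymous")
  expect_equal(r97c$substitution_class, "transition")

  r248k <- annotate_coding_effect(a3d, v[v$label == "R248K", ])
  expect_equal(r248k$codon_number, 248)
  expect_equal(r248k$codon_position, 2L)
  expect_equal(c(r248k$ref_codon, r248k$alt_codon), c("AGG", "AAG"))
  expect_equal(c(r248k$ref_aa, r248k$alt_aa), c("R", "K"))

  l221l <- annotate_coding_effect(a3d, v[v$label == "L221L", ])
  expect_equal(c(l221l$ref_codon, l221l$alt_codon), c("CTG", "CTC"))
  expect_equal(l221l$effect_class, "synonymous")
  expect_equal(l221l$substitution_class, "transversion")

  n15 <- annotate_coding_effect(synthetic_cds("A3H"), v[v$label == "N15del", ])
  expect_equal(n15$codon_number, 15)
  expect_equal(n15$ref_aa, "N")
  expect_equal(n15$effect_class, "inframe_deletion")
  expect_equal(n15$substitution_class, "indel")
})

test_that("annotation rejects a CDS/reference mismatch with a clear message", {
  v <- apobec3_variants()
  wrong <- v[v$label == "R97C", ]
  wrong$ref <- "G"
  expect_error(annotate_coding_effect(synthetic_cds("A3D"), wrong),
               "expected 'G', CDS has 'C'")
})

test_that("swapping ref and alt alleles swaps amino acids but preserves codon and class", {
  v <- annotate_variant_table()
  snvs <- v[v$effect != "inframe_deletion", ]
  for (i in seq_len(nrow(snvs))) {
    def <- snvs[i, ]
    cds <- as.character(synthetic_cds(def$transcript_id))
    # install the alt allele into the CDS, then annotate the reverse variant
    substr(cds, def$cds_pos, def$cds_pos) <- def$alt
    rev_def <- def
    rev_def$ref <- def$alt
    rev_def$alt <- def$ref
    eff <- annotate_coding_effect(cds, rev_def)
    expect_equal(eff$codon_number, def$codon_number)
    expect_equal(c(eff$ref_aa, eff$alt_aa), c(def$alt_aa, def$ref_aa))
    expect_equal(eff$substitution_class, def$substitution_class)
  }
})

test_that("transition and transversion exactly partition annotated SNVs", {
  v <- annotate_variant_table()
  snvs <- v[v$effect != "inframe_deletion", ]
  expect_true(all(snvs$substitution_class %in% c("transition", "transversion")))
  # independent purine/pyrimidine check
  pur <- c("A", "G")
  same <- (snvs$ref %in% pur) == (snvs$alt %in% pur)
  expect_equal(snvs$substitution_class == "transition", same)
  # annotated effect classes agree with the published classification
  expect_equal(snvs$effect_class, snvs$effect)
})
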