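#!/usr/bin/env Rscript
# Builds the deterministic study-cohort fixtures from the published summary
# tables and writes them as plain-text inputs for the downstream steps.
# Two reconstructions exist because the published per-variant genotype
# tallies and the per-sample haplotype categories disagree for A3H (see the
# methods vignette); each downstream analysis uses the reconstruction that
# matches what it re-derives.

suppressPackageStartupMessages(library(apobec3pop))

out_dir <- "results/fixtures"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

counts_fx <- fixture_from_printed_tables("genotype_counts")
cats_fx <- fixture_from_printed_tables("haplotype_categories")

for (g in names(counts_fx)) {
  write_genotype_table(counts_fx[[g]],
                       file.path(out_dir, paste0(g, "_counts.tsv")))
  write_genotype_table(cats_fx[[g]],
                       file.path(out_dir, paste0(g, "_categories.tsv")))
  write_cohort_vcf(counts_fx[[g]], file.path(out_dir, paste0(g, "_counts.vcf")))
}
write_synthetic_cds_fasta(file.path(out_dir, "apobec3_cds_synthetic.fasta"))

sizes <- vapply(counts_fx, function(cc) length(cc$samples), integer(1))
cat("Fixture cohorts written to", out_dir, "\n")
cat("Per-gene sample sizes:",
    paste(sprintf("%s=%d", names(sizes), sizes), collapse = ", "), "\n")
cat("Genotype tallies of the count fixtures match the published table",
    "exactly by construction; the category fixtures expand the published",
    "per-sample diplotype rows.\n")
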