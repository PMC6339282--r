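#!/usr/bin/env Rscript
# Diplotype assignment and A3H stability classification. The category
# fixtures drive the per-sample assignment summary (the shape of the
# published haplotype-frequency table); the count fixture drives the A3H
# stability headline, whose denominator is the published site-15 genotype
# tally (29/49/55 of 133).

suppressPackageStartupMessages(library(apobec3pop))

dir.create("results", showWarnings = FALSE)
cats_fx <- fixture_from_printed_tables("haplotype_categories")

summaries <- list()
for (g in names(cats_fx)) {
  calls <- assign_diplotypes(cats_fx[[g]], g)
  s <- summarize_cohort(calls)
  cats <- cbind(gene = g, s$categories, n = s$n)
  cats$pct <- round_half_up(cats$pct, 1)
  summaries[[g]] <- cats
  cat(sprintf("%s (n = %d): %s\n", g, s$n,
              paste(sprintf("%s %.1f%%", s$categories$category,
                            round_half_up(s$categories$pct, 1)),
                    collapse = ", ")))
}
write.table(do.call(rbind, summaries), "results/haplotype_summary.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

count_fx <- fixture_cohort_from_counts("A3H")
calls <- assign_diplotypes(count_fx, "A3H")
s <- summarize_cohort(calls)
write.table(calls, "results/a3h_stability_calls.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf(
  "\nA3H stability (count fixture): %d of %d samples (%.1f%%) carry zero
stable haplotypes — every one a deletion homozygote at site 15 — and so
cannot express a stable A3H protein.\n",
  s$zero_stable$count, s$n, round_half_up(s$zero_stable$pct, 1)))
cat("Wrote results/haplotype_summary.tsv and results/a3h_stability_calls.tsv\n")
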