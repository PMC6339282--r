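Package: apobec3pop
Title: Population Genetics of APOBEC3 Coding Variation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing coding variation in the APOBEC3
    cytidine deaminase genes (A3D, A3F, A3G, A3H) in diploid cohorts:
    genotype-table and minimal-VCF ingest, coding-effect annotation in CDS
    coordinates, allele frequencies and Hardy-Weinberg chi-squared testing,
    cross-population allele-frequency comparison (Fisher's exact and
    chi-squared), pairwise linkage disequilibrium with EM haplotype-frequency
    estimation from unphased genotypes, rule-based diplotype assignment with
    a confirmed/unconfirmed phase rule, and APOBEC3H protein-stability
    classification. Ships deterministic fixture cohorts reconstructed from
    published summary tables and a synthetic-cohort simulator with an
    inbreeding-coefficient deviation knob.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    vcfR,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
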