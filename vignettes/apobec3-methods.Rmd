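---
title: "Methods: population genetics of APOBEC3 coding variation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population genetics of APOBEC3 coding variation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apobec3pop)
```

## The problem

The APOBEC3 genes (A3D, A3F, A3G, A3H, chromosome 22) encode cytidine
deaminases that restrict retroviruses, including HIV-1, by hypermutating
viral cDNA during reverse transcription; HIV-1's Vif protein counteracts
them. Coding polymorphisms in these genes modulate restriction. For A3H
the consequences are drastic: of the named haplotypes at the five canonical
amino-acid positions 15, 18, 105, 121 and 178, only II, V and VII encode
proteins stable enough to restrict HIV-1, while haplotypes carrying the
asparagine-15 deletion (III, IV, X among them) and haplotypes I and VI are
unstable. An individual whose two A3H haplotypes are both unstable cannot
mount A3H-mediated restriction at all.

This package implements the statistical characterization of such variation
in a diploid cohort genotyped at a handful of biallelic coding sites per
gene: genotype tallies, Hardy--Weinberg equilibrium (HWE) testing,
cross-population allele-frequency comparison, pairwise linkage
disequilibrium (LD), rule-based diplotype assignment, and A3H stability
classification. It ships deterministic fixture cohorts reconstructed from
the summary tables of a published study of 192 HIV-1-positive individuals
from northern South Africa (per-gene sequencing success 168/154/165/133),
so the whole pipeline is exercisable without any data download.

## Coordinates and variant model

All positions are 1-based nucleotides in the coding sequence (CDS) of a
named transcript; genomic coordinates and strand never enter. A variant is
biallelic with `ref`/`alt` allele strings; unequal lengths encode indels.
Genotypes are **unordered** allele pairs stored as alt-allele dosage
(0/1/2, `NA` missing); phase in VCF input is discarded, because the
short-read genotypes the pipeline ingests are unphased.

For an SNV at CDS position $p$, the affected codon is
$\lceil p/3 \rceil$ with within-codon offset $((p-1) \bmod 3)+1$;
translation uses the standard genetic code, `synonymous` iff the amino acid
is unchanged, and the substitution is a `transition` iff both alleles are
purines or both pyrimidines. The A3H N15 deletion is modeled as ref
`"AAC"` / alt `"-"` spanning CDS 43--45. The deleted residue sits in a
Gln--Asn codon pair (`CAA AAC`), so the three deleted bases are
alignment-ambiguous within the repeat; some displays print the
left-aligned `CAA` representation of the same event. Deletions of length
divisible by three are `inframe_deletion`, anything else `frameshift`.

Because full Ensembl transcripts are not redistributed, the package builds
**synthetic CDS fixtures**: sequences carrying the exact study codons at
the correct codon numbers and a neutral alanine codon elsewhere
(`synthetic_cds()`, shipped as
`inst/extdata/apobec3_cds_synthetic.fasta`). They exist purely so the
annotator is testable; transcript identifiers are metadata.

## Per-variant statistics

With genotype counts $(n_{RR}, n_{RA}, n_{AA})$, $n$ their sum and
$p = (2n_{RR}+n_{RA})/2n$ the reference-allele frequency, the HWE test
compares observed counts with $(p^2 n,\ 2pq\,n,\ q^2 n)$ by
$\chi^2 = \sum (O-E)^2/E$ at **one degree of freedom, no continuity
correction, no class pooling** — the convention under which all 32
published A3D/A3F/A3G test statistics reproduce to printed precision
(e.g. 0.001, 4.02, 7.04, 6.09, 0.73). A correction flag exists but
defaults off. Monomorphic sites report $\chi^2 = 0$, $p = 1$, flagged
`monomorphic`. The published A3H statistics do **not** reproduce from the
published genotype tallies under any 1-df convention (the deletion row
recomputes to about 7.3 against a printed 10.25); the package reports its
own full-precision values for those rows and they are not pinned in tests.

Internal values are never rounded; report formatting rounds half away from
zero (`round_half_up()`), 1 decimal for percentages, matching how the
study tables print.

### Site-frequency threshold: carrier vs allele basis

Haplotype assignment considers nonsynonymous, previously reported sites
whose frequency reaches 5%. The study describes this as a minor-allele
frequency (MAF) filter, but its printed site lists only reproduce when the
threshold is applied to the **carrier frequency** (fraction of subjects
with at least one alternate allele): A3D T238A has allele MAF 4.2% yet is
a haplotype site, as are A3F R48P (3.9%) and Y307C (4.9%).
`considered_sites()` therefore supports both bases with `carrier` as the
default, and the shipped per-gene haplotype tables pin the exact printed
site lists as configuration. Novel variants (no database identifier) are
excluded from sites even above threshold, again matching the printed
tables; a flag can include them. For A3H the five canonical sites are
always used: K140E is excluded as fixed in every population surveyed
(alternate-homozygous in all 133 subjects and in all references, most
plausibly a reference-genome artifact), and T43T as synonymous.

## Cross-population comparison

Reference populations publish only percentages and chromosome counts
($2n$), so integer allele counts are reconstructed by rounding
$\mathrm{alt\%} \times 2n / 100$ half away from zero; the reconstruction
is reported next to each p-value so exact counts can be substituted when
available. The cohort-vs-reference 2×2 allele table is tested with:

* **Fisher's exact test**, two-sided by the point-probability rule (sum of
  hypergeometric probabilities of all tables with the observed margins no
  more likely than the observed one, with a $1+10^{-7}$ tie tolerance),
  computed in log space via `dhyper` so ExAC-sized margins would not
  overflow. This is the convention of the online calculator used by the
  study; mid-p and twice-one-tail variants give different values.
* **Pearson chi-squared** (1 df, no correction) for very large references,
  cutoff $2n > 10{,}000$ — which assigns exactly ExAC among the shipped
  references. Exact enumeration is unnecessary at that scale: on balanced
  tables with margins in the thousands the two tests agree within a few
  percent relative, though on cohort-scale tables (cells of tens to
  hundreds) the discreteness of the exact test leaves per-table relative
  differences of 10--20%, so the tests only assert median-level agreement
  there. A zero-margin table (variant fixed in both groups) falls back to
  Fisher, where $p = 1$.

Significance is flagged at $p \le 0.05$ with **no multiple-testing
correction**, mirroring the source tables as a faithful-reproduction
choice, not a statistical endorsement; a Bonferroni option exists but
defaults off. Exact reproduction of the published reference p-values is
not pinned: whether they were computed from rounded or exact reference
counts is not recorded, and rounding moves borderline values.

## Linkage disequilibrium and the two-locus EM

With two-locus haplotype frequencies $f_{AB}, f_{Ab}, f_{aB}, f_{ab}$ and
allele frequencies $p_A, p_B$:

$$D = f_{AB} - p_A p_B, \qquad
D' = |D| / D_\max, \qquad
R^2 = \frac{D^2}{p_A q_A\, p_B q_B},$$

where $D_\max$ is the admissible extreme given the margins
($\min(p_A q_B, q_A p_B)$ for $D>0$, else $\min(p_A p_B, q_A q_B)$). The
goodness-of-fit statistic is $\chi^2 = R^2 \cdot n$ on $n$ chromosomes
(two per sample with calls at both loci), 1 df.

Unphased genotypes determine the gametes of every genotype class except
the double heterozygote. The EM algorithm resolves that one ambiguity; the
allele frequencies are margin-fixed, leaving a single free parameter
($f_{AB}$). For small tables that one-dimensional likelihood can be
multimodal, and a single equilibrium-initialized run can stall on a local
optimum, so `em_haplotype_freqs()` runs **three deterministic starts** —
the linkage-equilibrium point plus the two phase-extreme (cis/trans)
neighbourhoods — and returns the highest-likelihood solution
(log-likelihood non-decreasing within each run; tolerance $10^{-8}$ on the
log-likelihood, at most 1000 iterations per start; non-convergence is
flagged, not raised). When the cis and trans runs tie in likelihood but
disagree — the fully phase-ambiguous case, e.g. a table containing only
double heterozygotes — the data carry no information on the sign of $D$
and the equilibrium solution ($D = 0$) is returned by convention. Tests
verify the EM against an exhaustive likelihood grid at $10^{-3}$
resolution on small tables and against simulated truth at $n = 2000$.

The LD report flags pairs at $R^2 > 0.1$ and prints $D'$ alongside, since
a bare cutoff of 0.1 does not say which statistic it applies to. One
caution: within-gene LD computed on the **fixture** cohorts reflects the
deterministic reconstruction layout, not measured LD — the published
summary tables constrain only per-variant tallies, not joint patterns.
Reproducing the study's own LD values (e.g. $D' = 1$, $R^2 = 0.122$ and
$R^2 = 0.108$ for its two flagged pairs) requires 1000 Genomes phase-3
haplotypes; the recipe is: extract the two rsIDs from the 1000G panel,
tabulate phased haplotype counts, and call `ld_from_haplotypes()` — no
download is performed by the package or its tests.

## Diplotype assignment and A3H stability

Per sample, over the gene's considered sites: missing anywhere →
`no_call`; otherwise count heterozygous sites. With **at most one**
heterozygous site the unordered haplotype pair is phase-free and the call
is `confirmed`; the two haplotypes are labelled from the gene's haplotype
table, with unknown combinations minted deterministic `novel-…` labels
encoding the alt-allele pattern in site order. With two or more
heterozygous sites phase is ambiguous and the call is `unconfirmed` (no
statistical phasing is attempted). A sample reference-homozygous at every
considered site that carries some excluded-site variant is categorized
`minor_variant` (known nonsynonymous below threshold) or `other`
(synonymous or novel), mirroring the published category split; such
samples stay in the denominator.

A3H stability: any haplotype carrying the 15-deletion is unstable;
labelled haplotypes take their table stability (II stable; I, III, IV
unstable; X unstable via the deletion); anything else is unknown. The
per-sample count of stable haplotypes is 0, 1, 2 or `unknown`; a sample
**homozygous for the deletion has zero stable haplotypes regardless of
phase**, so that resolution applies even to unconfirmed calls. One printed
A3G category labels a 363R-heterozygote row as a homozygous pair; the
genotype implies the pair i/iv and the assignment emits i/iv (the printed
label is treated as a typographical slip, not emulated).

## The fixture cohorts, and why there are two

The published per-variant genotype tallies and the published per-sample
diplotype categories are **mutually inconsistent for A3H**: the category
rows imply site-15 tallies of 38 hom-ref / 47 het / 38 hom-del (plus 10
uncategorized) out of 133, while the per-variant table prints 29/49/55. No
single cohort can satisfy both, so the package builds both
reconstructions and each analysis uses the one matching what it re-derives:

* `fixture_cohort_from_counts()` — deterministic margin assembly whose
  per-variant tallies equal the published counts exactly. Used for
  frequencies, HWE, population comparison, and the stability headline:
  41.4% (55/133) of samples have zero stable haplotypes, exactly the
  deletion homozygotes. Joint patterns are underdetermined by the
  published margins; the layout places the rare reference alleles at
  sites 105/121/178 on deletion heterozygotes, so those few samples
  resolve to `unknown` stability (their haplotypes fall outside the four
  combinations the study reports) rather than inventing extra zero-stable
  samples.
* `fixture_cohort_from_categories()` — verbatim expansion of each printed
  category row into that many identical samples. Used for
  diplotype-assignment summaries: 28.6% (38/133) confirmed II/II.
  "Minor variant" and "Other" rows, whose per-sample detail is not
  published, are expanded as reference-homozygous at the haplotype sites
  plus one designated excluded-site heterozygote.

## The cohort simulator

`simulate_cohort()` emulates the sampling structure the analysis assumes:
per sample and gene, the whole gene is missing with the study's per-gene
failure probability (24/38/27/59 of 192 by default); otherwise two
haplotypes are drawn from the gene's frequency vector — independently with
probability $1-F$, identical by descent with probability $F$ — and
unphased genotypes are emitted. The single inbreeding coefficient $F$ is
the HWE-deviation knob ($F=0$ equilibrium, $F=1$ no heterozygotes). The
drawn haplotype labels (hidden truth) are kept as an attribute and written
only to a sidecar file, never into genotype exports.

Default haplotype frequencies are calibrated to the study cohort: for
A3D/A3F/A3G, the haplotype tallies over the confirmed categories. For A3H
the confirmed categories alone imply a deletion-allele frequency of
exactly 50%, which contradicts the cohort's measured 59.8%; the default
instead fixes the deletion side at 59.8% and splits it across III/IV/X in
their confirmed-category proportions, with the remainder on II. The
simulator draws genotypes at the haplotype-defining sites only, under HWE
(or the $F$ deviation) and free recombination between genes; it does not
emulate sequencing error, variant-calling noise, within-gene LD beyond
what the haplotype structure induces, or real population substructure —
so passing calibration tests demonstrates estimator correctness under the
stated model, not robustness to upstream artifacts.

Simulation-based checks in the test suite use cohort-scale problem sizes:
1000 replicates of 192 samples for the HWE type-I rate (observed ≈ 0.046
at nominal 0.05), 2000 samples for EM recovery, $10^5$ samples for
frequency convergence.

## Known limitations

* The two fixture reconstructions cannot be unified (source-table
  inconsistency above); each headline number is tied to the
  reconstruction that supports it.
* Reference allele counts are reconstructed from rounded percentages;
  borderline published p-values need not reproduce exactly.
* No multi-locus (>2) EM or statistical phasing: samples with ≥2
  heterozygous considered sites stay `unconfirmed`, as in the source
  tables.
* Stability of A3H haplotypes beyond those observed here (V--IX, XI--XIII
  compositions) is not encoded; unknown combinations classify as
  `unknown` unless they carry the deletion.
* The chi-squared HWE test is asymptotic; with expected class counts
  below ~1 (several rare variants here) its printed p-values are rough,
  which the study's own tables share. An exact HWE test is a possible
  extension and deliberately out of scope.
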