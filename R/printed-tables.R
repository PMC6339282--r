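# Published summary tables for the South African APOBEC3 cohort, embedded as
# configuration data. Variant coordinates are 1-based positions in the CDS of
# the transcript named in `transcript_id`; genomic coordinates are never used.
# The N15 deletion in A3H is carried as a biallelic indel with the deletion
# allele written as "-".

#' Variant definitions for the APOBEC3 study loci
#'
#' One row per biallelic coding variant: gene, variant identifier (dbSNP rsID
#' or `"NI"` for variants not identified previously), amino-acid label,
#' transcript used for CDS numbering, 1-based CDS position, ref/alt alleles,
#' exon, and effect class. The A3H N15 deletion is encoded as ref `"AAC"` /
#' alt `"-"` spanning CDS 43-45 (one asparagine codon inside a Gln-Asn
#' repeat; the deleted bases are alignment-ambiguous within the repeat).
#'
#' @return data.frame with columns `gene`, `label`, `variant_id`,
#'   `transcript_id`, `cds_pos`, `ref`, `alt`, `exon`, `effect`, `novel`.
#' @export
apobec3_variants <- function() {
  v <- rbind(
    # gene  label    variant_id     transcript          pos   ref    alt  exon effect
    c("A3D", "R6K",   "NI",          "ENST00000216099",  17, "G",   "A", 1, "nonsynonymous"),
    c("A3D", "R97C",  "rs75858538",  "ENST00000216099", 289, "C",   "T", 1, "nonsynonymous"),
    c("A3D", "L221R", "NI",          "ENST00000216099", 662, "T",   "G", 5, "nonsynonymous"),
    c("A3D", "C224Y", "rs772893975", "ENST00000216099", 671, "G",   "A", 5, "nonsynonymous"),
    c("A3D", "T238A", "rs201709403", "ENST00000216099", 712, "A",   "G", 5, "nonsynonymous"),
    c("A3D", "T238I", "NI",          "ENST00000216099", 713, "C",   "T", 5, "nonsynonymous"),
    c("A3D", "R248K", "rs61748819",  "ENST00000216099", 743, "G",   "A", 5, "nonsynonymous"),
    c("A3D", "C320Y", "rs61999342",  "ENST00000216099", 959, "G",   "A", 6, "nonsynonymous"),
    c("A3D", "L221L", "rs769426665", "ENST00000216099", 663, "G",   "C", 5, "synonymous"),
    c("A3D", "T316T", "rs184448269", "ENST00000216099", 948, "C",   "T", 6, "synonymous"),
    c("A3F", "R48P",  "rs35053197",  "ENST00000308521", 143, "G",   "C", 2, "nonsynonymous"),
    c("A3F", "A78V",  "rs5750728",   "ENST00000308521", 233, "C",   "T", 4, "nonsynonymous"),
    c("A3F", "I87L",  "rs146543452", "ENST00000308521", 259, "A",   "C", 4, "nonsynonymous"),
    c("A3F", "Q87L",  "rs114704208", "ENST00000381565", 260, "A",   "T", 3, "nonsynonymous"),
    c("A3F", "A108S", "rs2020390",   "ENST00000308521", 322, "G",   "T", 4, "nonsynonymous"),
    c("A3F", "V231I", "rs2076101",   "ENST00000308521", 691, "G",   "A", 5, "nonsynonymous"),
    c("A3F", "Y307C", "rs12157816",  "ENST00000308521", 920, "A",   "G", 6, "nonsynonymous"),
    c("A3F", "I117I", "NI",          "ENST00000308521", 351, "C",   "T", 4, "synonymous"),
    c("A3F", "S118S", "rs35928287",  "ENST00000308521", 354, "C",   "T", 4, "synonymous"),
    c("A3F", "R143R", "rs4821862",   "ENST00000308521", 429, "C",   "T", 4, "synonymous"),
    c("A3F", "Y196Y", "rs765418322", "ENST00000308521", 588, "T",   "C", 4, "synonymous"),
    c("A3F", "S229S", "rs549550231", "ENST00000308521", 687, "A",   "G", 5, "synonymous"),
    c("A3F", "E245E", "rs113109079", "ENST00000308521", 735, "G",   "A", 5, "synonymous"),
    c("A3F", "S327S", "rs35895636",  "ENST00000308521", 981, "C",   "T", 5, "synonymous"),
    c("A3G", "H186R", "rs8177832",   "ENST00000407997", 557, "A",   "G", 4, "nonsynonymous"),
    c("A3G", "R256H", "rs17000736",  "ENST00000407997", 767, "G",   "A", 6, "nonsynonymous"),
    c("A3G", "Q275E", "rs17496046",  "ENST00000407997", 823, "C",   "G", 6, "nonsynonymous"),
    c("A3G", "G363R", "rs148267053", "ENST00000407997", 1087, "G",  "A", 7, "nonsynonymous"),
    c("A3G", "S60S",  "rs112603901", "ENST00000407997", 180, "C",   "T", 3, "synonymous"),
    c("A3G", "A109A", "rs375760983", "ENST00000407997", 327, "C",   "T", 3, "synonymous"),
    c("A3G", "F119F", "rs5757465",   "ENST00000407997", 357, "T",   "C", 3, "synonymous"),
    c("A3G", "L371L", "rs11545130",  "ENST00000407997", 1111, "C",  "T", 7, "synonymous"),
    c("A3H", "N15del", "rs140936762", "ENST00000442487", 43, "AAC", "-", 1, "inframe_deletion"),
    c("A3H", "R18L",  "rs139293",    "ENST00000442487",  53, "G",   "T", 1, "nonsynonymous"),
    c("A3H", "G105R", "rs139297",    "ENST00000442487", 313, "G",   "C", 2, "nonsynonymous"),
    c("A3H", "K121E", "rs139298",    "ENST00000442487", 361, "A",   "G", 2, "nonsynonymous"),
    c("A3H", "K140E", "rs139300",    "ENST00000442487", 418, "A",   "G", 2, "nonsynonymous"),
    c("A3H", "E178D", "rs139302",    "ENST00000442487", 534, "G",   "C", 3, "nonsynonymous"),
    c("A3H", "T43T",  "rs139294",    "ENST00000442487", 129, "G",   "C", 1, "synonymous")
  )
  out <- data.frame(
    gene = v[, 1], label = v[, 2], variant_id = v[, 3], transcript_id = v[, 4],
    cds_pos = as.integer(v[, 5]), ref = v[, 6], alt = v[, 7],
    exon = as.integer(v[, 8]), effect = v[, 9],
    stringsAsFactors = FALSE
  )
  out$novel <- out$variant_id == "NI"
  out
}

#' Published per-variant genotype tallies for the study cohort
#'
#' Genotype counts (hom-ref, het, hom-alt) per variant, over the samples
#' successfully sequenced for each gene (A3D 168, A3F 154, A3G 165, A3H 133
#' of 192 subjects).
#'
#' @return data.frame with columns `gene`, `label`, `n_rr`, `n_ra`, `n_aa`.
#' @export
apobec3_genotype_counts <- function() {
  g <- rbind(
    c("A3D", "R6K",   151, 17, 0),
    c("A3D", "R97C",  148, 19, 1),
    c("A3D", "L221R", 165, 3, 0),
    c("A3D", "C224Y", 161, 7, 0),
    c("A3D", "T238A", 154, 14, 0),
    c("A3D", "T238I", 160, 8, 0),
    c("A3D", "R248K", 133, 33, 2),
    c("A3D", "C320Y", 167, 1, 0),
    c("A3D", "L221L", 165, 3, 0),
    c("A3D", "T316T", 161, 7, 0),
    c("A3F", "R48P",  142, 12, 0),
    c("A3F", "A78V",  95, 56, 3),
    c("A3F", "I87L",  153, 1, 0),
    c("A3F", "Q87L",  145, 9, 0),
    c("A3F", "A108S", 54, 84, 16),
    c("A3F", "V231I", 122, 30, 2),
    c("A3F", "Y307C", 139, 15, 0),
    c("A3F", "I117I", 152, 2, 0),
    c("A3F", "S118S", 113, 41, 0),
    c("A3F", "R143R", 19, 91, 44),
    c("A3F", "Y196Y", 126, 24, 4),
    c("A3F", "S229S", 152, 2, 0),
    c("A3F", "E245E", 146, 7, 1),
    c("A3F", "S327S", 128, 23, 3),
    c("A3G", "H186R", 63, 82, 20),
    c("A3G", "R256H", 161, 4, 0),
    c("A3G", "Q275E", 111, 49, 5),
    c("A3G", "G363R", 148, 17, 0),
    c("A3G", "S60S",  147, 18, 0),
    c("A3G", "A109A", 164, 1, 0),
    c("A3G", "F119F", 164, 1, 0),
    c("A3G", "L371L", 158, 7, 0),
    c("A3H", "N15del", 29, 49, 55),
    c("A3H", "R18L",  112, 15, 6),
    c("A3H", "G105R", 1, 4, 128),
    c("A3H", "K121E", 1, 6, 126),
    c("A3H", "K140E", 0, 0, 133),
    c("A3H", "E178D", 3, 11, 119),
    c("A3H", "T43T",  6, 7, 120)
  )
  data.frame(
    gene = g[, 1], label = g[, 2],
    n_rr = as.integer(g[, 3]), n_ra = as.integer(g[, 4]),
    n_aa = as.integer(g[, 5]), stringsAsFactors = FALSE
  )
}

# Reference-population chromosome counts (2n) from the published comparison
# table: five 1000 Genomes superpopulations plus the ExAC exome aggregate.
REFPOP_2N <- c(EAS = 1008L, EUR = 1006L, AFR = 1322L, AMR = 694L,
               SAS = 978L, ExAC = 121412L)

#' Published reference-population allele frequencies
#'
#' Long-format table of ref/alt allele percentages per variant and reference
#' population, as published (1000 Genomes superpopulations EAS/EUR/AFR/AMR/SAS
#' and ExAC). Variants without a published frequency carry `NA` percentages
#' and a `missing_reason` of `"NI"` (not identified previously) or `"ND"`
#' (not determined in the reference database).
#'
#' @return data.frame with columns `gene`, `label`, `population`, `two_n`,
#'   `ref_pct`, `alt_pct`, `missing_reason`.
#' @export
apobec3_reference_freqs <- function() {
  # per variant: list of c(EAS ref, alt, EUR ref, alt, AFR, ..., AMR, SAS, ExAC)
  # NA encodes NI/ND, disambiguated by the `na` field.
  row <- function(gene, label, freqs, na = "ND") {
    list(gene = gene, label = label, freqs = freqs, na = na)
  }
  ni6 <- rep(NA_real_, 12)
  rows <- list(
    row("A3D", "R6K",   ni6, na = "NI"),
    row("A3D", "R97C",  c(100, 0, 100, 0, 96.6, 3.4, 100, 0, 100, 0, 99.7, 0.3)),
    row("A3D", "L221R", ni6, na = "NI"),
    row("A3D", "C224Y", c(rep(NA_real_, 10), 100, 0)),
    row("A3D", "T238A", c(100, 0, 100, 0, 100, 0, 100, 0, 100, 0, 100, 0)),
    row("A3D", "T238I", ni6, na = "NI"),
    row("A3D", "R248K", c(100, 0, 100, 0, 89, 11, 99, 1, 100, 0, 99, 1)),
    row("A3D", "C320Y", c(rep(NA_real_, 10), 100, 0)),
    row("A3D", "L221L", c(rep(NA_real_, 10), 100, 0)),
    row("A3D", "T316T", c(100, 0, 100, 0, 98.8, 1.2, 99.6, 0.4, 100, 0, 99.9, 0.1)),
    row("A3F", "R48P",  c(100, 0, 100, 0, 96.9, 3.1, 99.4, 0.6, 99.4, 0.6, 99.7, 0.3)),
    row("A3F", "A78V",  c(29, 71, 51, 49, 80, 20, 38, 62, 39, 61, 52.3, 47.8)),
    row("A3F", "I87L",  c(100, 0, 100, 0, 99, 1, 100, 0, 100, 0, 100, 0)),
    row("A3F", "Q87L",  c(100, 0, 100, 0, 94.5, 5.5, 99.6, 0.4, 100, 0, 99.7, 0.3)),
    row("A3F", "A108S", c(29, 71, 51, 49, 68, 32, 37, 63, 40, 60, 52.4, 47.6)),
    row("A3F", "V231I", c(29, 71, 51, 49, 81, 19, 38, 62, 39, 61, 48.4, 51.6)),
    row("A3F", "Y307C", c(100, 0, 98, 2, 97, 3, 98, 2, 100, 0, 98.7, 1.3)),
    row("A3F", "I117I", ni6, na = "NI"),
    row("A3F", "S118S", c(rep(NA_real_, 10), 99.7, 0.3)),
    row("A3F", "R143R", c(29, 71, 51, 49, 45, 55, 36, 64, 39, 61, 45.5, 54.6)),
    row("A3F", "Y196Y", c(rep(NA_real_, 10), 100, 0)),
    row("A3F", "S229S", c(rep(NA_real_, 10), 100, 0)),
    row("A3F", "E245E", c(100, 0, 100, 0, 99, 1, 100, 0, 100, 0, 100, 0)),
    row("A3F", "S327S", c(100, 0, 100, 0, 98.3, 1.7, 100, 0, 100, 0, 99.8, 0.2)),
    row("A3G", "H186R", c(92.8, 7.2, 97, 3, 57, 43, 92.5, 7.5, 99.2, 0.8, 93.6, 6.4)),
    row("A3G", "R256H", c(100, 0, 100, 0, 98.6, 1.4, 100, 0, 100, 0, 100, 0)),
    row("A3G", "Q275E", c(97.3, 2.7, 94.6, 5.4, 87.5, 12.5, 96, 4, 98.7, 1.3, 94.3, 5.7)),
    row("A3G", "G363R", c(100, 0, 100, 0, 98.6, 1.4, 99.9, 0.1, 100, 0, 100, 0)),
    row("A3G", "S60S",  c(100, 0, 100, 0, 99.7, 0.3, 100, 0, 100, 0, 100, 0)),
    row("A3G", "A109A", c(rep(NA_real_, 10), 100, 0)),
    row("A3G", "F119F", c(77.6, 22.4, 55.3, 44.7, 97.1, 2.9, 60.2, 39.8, 55.5, 44.5, 62.8, 37.2)),
    row("A3G", "L371L", c(100, 0, 100, 0, 97, 3, 99.6, 0.4, 100, 0, 99.7, 0.3)),
    row("A3H", "N15del", c(74, 26, 66, 34, 69, 31, 72, 28, 60, 40, 65.7, 34.3)),
    row("A3H", "R18L",  c(84.1, 15.9, 70.7, 29.3, 93, 7, 75.8, 24.2, 69.4, 30.6, 73.2, 26.8)),
    row("A3H", "G105R", c(68.5, 31.5, 53.6, 46.4, 12.5, 87.5, 61.7, 38.3, 57.1, 42.9, 51.9, 48.1)),
    row("A3H", "K121E", c(68.5, 31.5, 52.3, 47.7, 12.5, 87.5, 61.2, 38.8, 56.1, 43.9, 51.5, 48.5)),
    row("A3H", "K140E", c(0, 100, 0, 100, 0, 100, 0, 100, 0, 100, 0, 100)),
    row("A3H", "E178D", c(67, 33, 54.6, 45.4, 15.3, 84.7, 65.4, 34.6, 56.1, 43.9, 52.3, 47.7)),
    row("A3H", "T43T",  c(66.7, 33.3, 54.6, 45.4, 17.2, 82.8, 62, 38, 56, 44, 52.4, 47.6))
  )
  pops <- names(REFPOP_2N)
  out <- do.call(rbind, lapply(rows, function(r) {
    ref <- r$freqs[seq(1, 11, by = 2)]
    alt <- r$freqs[seq(2, 12, by = 2)]
    data.frame(
      gene = r$gene, label = r$label, population = pops,
      two_n = unname(REFPOP_2N),
      ref_pct = ref, alt_pct = alt,
      missing_reason = ifelse(is.na(ref), r$na, ""),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

# --- haplotype configuration -------------------------------------------------

#' Named haplotype tables for the four APOBEC3 genes
#'
#' The per-gene haplotype tables used for diplotype labelling. Sites are the
#' gene's published haplotype-defining variants (by amino-acid label, ordered
#' by CDS position); alleles are `"ref"`/`"alt"` at each site. Labels follow
#' the study's own i-iv nomenclature for A3D/A3F/A3G (haplotype i is the
#' GRCh37 reference combination) and the established I-XIII nomenclature at
#' the five canonical sites for A3H. `stability` is meaningful for A3H only:
#' haplotypes II, V and VII encode stable proteins; I, III, IV and VI are
#' unstable, as is any haplotype carrying the N15 deletion; the remainder are
#' unknown.
#'
#' @return named list of data.frames (one per gene) with columns `label`,
#'   one column per site, and `stability`.
#' @export
apobec3_haplotype_tables <- function() {
  hap <- function(label, alleles, stability = "unknown") {
    c(list(label = label), as.list(alleles), list(stability = stability))
  }
  build <- function(sites, defs) {
    rows <- lapply(defs, function(d) {
      stopifnot(length(d$alleles) == length(sites))
      names(d$alleles) <- sites
      as.data.frame(c(list(label = d$label), as.list(d$alleles),
                      list(stability = d$stability)),
                    stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  list(
    A3D = build(c("R97C", "T238A", "R248K"), list(
      list(label = "i",   alleles = c("ref", "ref", "ref"), stability = "unknown"),
      list(label = "ii",  alleles = c("alt", "ref", "ref"), stability = "unknown"),
      list(label = "iii", alleles = c("ref", "alt", "ref"), stability = "unknown"),
      list(label = "iv",  alleles = c("ref", "ref", "alt"), stability = "unknown")
    )),
    A3F = build(c("R48P", "A78V", "A108S", "V231I", "Y307C"), list(
      list(label = "i",   alleles = c("ref", "ref", "ref", "ref", "ref"), stability = "unknown"),
      list(label = "iii", alleles = c("ref", "ref", "alt", "ref", "ref"), stability = "unknown"),
      list(label = "iv",  alleles = c("ref", "ref", "ref", "ref", "alt"), stability = "unknown"),
      list(label = "vi",  alleles = c("ref", "alt", "alt", "ref", "ref"), stability = "unknown")
    )),
    A3G = build(c("H186R", "Q275E", "G363R"), list(
      list(label = "i",   alleles = c("ref", "ref", "ref"), stability = "unknown"),
      list(label = "ii",  alleles = c("alt", "ref", "ref"), stability = "unknown"),
      list(label = "iii", alleles = c("ref", "alt", "ref"), stability = "unknown"),
      list(label = "iv",  alleles = c("ref", "ref", "alt"), stability = "unknown")
    )),
    # A3H canonical sites: 15 (N/del), 18 (R/L), 105 (G/R), 121 (K/E), 178 (E/D).
    # ref = GRCh37 allele at each site (N, R, G, K, E).
    A3H = build(c("N15del", "R18L", "G105R", "K121E", "E178D"), list(
      list(label = "I",   alleles = c("ref", "ref", "ref", "ref", "ref"), stability = "unstable"),
      list(label = "II",  alleles = c("ref", "ref", "alt", "alt", "alt"), stability = "stable"),
      list(label = "III", alleles = c("alt", "ref", "alt", "alt", "alt"), stability = "unstable"),
      list(label = "IV",  alleles = c("alt", "alt", "alt", "alt", "alt"), stability = "unstable"),
      list(label = "X",   alleles = c("alt", "ref", "alt", "alt", "ref"), stability = "unstable")
    ))
  )
}

#' Published per-sample haplotype categories
#'
#' The per-gene diplotype category rows of the published haplotype-frequency
#' table: each row is a multi-site genotype pattern (`0` hom-ref, `1` het,
#' `2` hom-alt at the gene's haplotype sites, in table order), the number of
#' individuals printed for it, and its printed status. `carries` names the
#' excluded-site variant placed on "minor variant" and "other" samples when
#' the category is expanded into a per-sample fixture (the publication does
#' not print per-sample detail for those rows; one designated excluded-site
#' heterozygote is used as a placeholder).
#'
#' @return data.frame with columns `gene`, `pattern` (comma-separated genotype
#'   codes at the gene's haplotype sites), `count`, `status` (`confirmed`,
#'   `unconfirmed`, `minor_variant`, `other`), `printed_pair`, `carries`.
#' @export
apobec3_haplotype_categories <- function() {
  r <- function(gene, pattern, count, status, pair = "", carries = "") {
    data.frame(gene = gene, pattern = pattern, count = as.integer(count),
               status = status, printed_pair = pair, carries = carries,
               stringsAsFactors = FALSE)
  }
  out <- rbind(
    # A3D: sites R97C, T238A, R248K
    r("A3D", "0,0,0", 88, "confirmed", "i/i"),
    r("A3D", "2,0,0", 1, "confirmed", "ii/ii"),
    r("A3D", "1,0,0", 18, "confirmed", "i/ii"),
    r("A3D", "0,1,0", 10, "confirmed", "i/iii"),
    r("A3D", "0,0,2", 1, "confirmed", "iv/iv"),
    r("A3D", "0,0,1", 27, "confirmed", "i/iv"),
    r("A3D", "0,0,0", 7, "minor_variant", carries = "C224Y"),
    r("A3D", "0,0,0", 16, "other", carries = "R6K"),
    # A3F: sites R48P, A78V, A108S, V231I, Y307C
    r("A3F", "0,0,0,0,0", 5, "confirmed", "i/i"),
    r("A3F", "0,0,2,0,0", 2, "confirmed", "iii/iii"),
    r("A3F", "0,0,1,0,0", 32, "confirmed", "i/iii"),
    r("A3F", "0,0,0,0,1", 5, "confirmed", "i/iv"),
    r("A3F", "0,2,2,0,0", 1, "confirmed", "vi/vi"),
    r("A3F", "0,1,2,0,0", 2, "confirmed", "iii/vi"),
    r("A3F", "0,0,0,0,0", 5, "minor_variant", carries = "Q87L"),
    r("A3F", "0,0,0,0,0", 51, "other", carries = "I117I"),
    r("A3F", "0,1,1,0,0", 21, "unconfirmed"),
    r("A3F", "0,1,1,1,0", 14, "unconfirmed"),
    r("A3F", "0,1,2,1,0", 8, "unconfirmed"),
    r("A3F", "0,1,1,2,0", 2, "unconfirmed"),
    r("A3F", "1,0,1,0,0", 6, "unconfirmed"),
    # A3G: sites H186R, Q275E, G363R. The published table labels the
    # 363R-heterozygote row "iv/iv"; the genotype implies the pair i/iv and
    # the assignment emits i/iv (suspected typographical error upstream).
    r("A3G", "0,0,0", 5, "confirmed", "i/i"),
    r("A3G", "2,0,0", 20, "confirmed", "ii/ii"),
    r("A3G", "1,0,0", 43, "confirmed", "i/ii"),
    r("A3G", "0,2,0", 3, "confirmed", "iii/iii"),
    r("A3G", "0,1,0", 22, "confirmed", "i/iii"),
    r("A3G", "0,0,1", 9, "confirmed", "i/iv"),
    r("A3G", "0,0,0", 11, "minor_variant", carries = "R256H"),
    r("A3G", "0,0,0", 52, "other", carries = "S60S"),
    # A3H: sites N15del, R18L, G105R, K121E, E178D
    r("A3H", "0,0,2,2,2", 38, "confirmed", "II/II"),
    r("A3H", "2,0,2,2,0", 25, "confirmed", "X/X"),
    r("A3H", "1,0,2,2,2", 36, "confirmed", "II/III"),
    r("A3H", "2,2,2,2,2", 6, "confirmed", "IV/IV"),
    r("A3H", "2,1,2,2,2", 7, "confirmed", "III/IV"),
    r("A3H", "0,0,0,0,0", 10, "other", carries = "T43T"),
    r("A3H", "1,0,2,1,2", 4, "unconfirmed"),
    r("A3H", "1,1,2,2,2", 7, "unconfirmed")
  )
  rownames(out) <- NULL
  out
}

#' Per-gene sample sizes of the study cohort
#'
#' Number of subjects successfully sequenced per gene, of 192 recruited.
#'
#' @return named integer vector.
#' @export
apobec3_gene_n <- function() {
  c(A3D = 168L, A3F = 154L, A3G = 165L, A3H = 133L)
}
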