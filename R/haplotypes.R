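# Diplotype assignment with the confirmed/unconfirmed phase rule: with at
# most one heterozygous site among a gene's considered (haplotype-defining)
# sites, the unordered haplotype pair is determined without phase
# information; with two or more heterozygous sites phase is ambiguous and the
# call is left unconfirmed. APOBEC3H haplotypes additionally carry a
# protein-stability annotation (II/V/VII stable; I/III/IV/VI and anything
# carrying the N15 deletion unstable).

#' Haplotype-defining sites for a gene
#'
#' Selects the sites used for diplotype assignment: nonsynonymous,
#' previously-reported variants whose frequency reaches `threshold_pct`,
#' ordered by CDS position. `basis` chooses the frequency scale: `"carrier"`
#' (percentage of subjects carrying the variant, the scale under which the
#' published site lists reproduce) or `"allele"` (minor allele frequency).
#' For A3H the five canonical haplotype-defining sites (15, 18, 105, 121,
#' 178) are always returned regardless of cohort frequencies; K140E (fixed
#' in all populations) and the synonymous T43T are excluded.
#'
#' @param cohort a [cohort_genotypes()] object.
#' @param gene gene identifier.
#' @param threshold_pct frequency threshold (percent).
#' @param basis `"carrier"` or `"allele"`.
#' @param include_novel include variants without a database identifier.
#' @return character vector of variant labels, ordered by CDS position.
#' @export
considered_sites <- function(cohort, gene, threshold_pct = 5,
                             basis = c("carrier", "allele"),
                             include_novel = FALSE) {
  basis <- match.arg(basis)
  if (identical(gene, "A3H")) {
    return(c("N15del", "R18L", "G105R", "K121E", "E178D"))
  }
  defs <- cohort$variants[cohort$variants$gene == gene, , drop = FALSE]
  defs <- defs[order(defs$cds_pos), , drop = FALSE]
  keep <- defs$effect %in% c("nonsynonymous", "inframe_deletion")
  if (!include_novel) keep <- keep & !defs$novel
  defs <- defs[keep, , drop = FALSE]
  freq <- vapply(defs$label, function(lab) {
    cc <- count_genotypes(cohort, lab)
    n <- sum(cc)
    if (n == 0L) return(0)
    if (basis == "carrier") {
      100 * (cc[["n_ra"]] + cc[["n_aa"]]) / n
    } else {
      allele_frequencies(cc)$maf_pct
    }
  }, numeric(1))
  defs$label[freq >= threshold_pct]
}

#' @noRd
hap_table_sites <- function(hap_table) {
  setdiff(colnames(hap_table), c("label", "stability"))
}

#' @noRd
mint_novel_label <- function(alleles) {
  paste0("novel-", paste(ifelse(alleles == "alt", "1", "0"), collapse = ""))
}

#' @noRd
lookup_hap_label <- function(alleles, hap_table) {
  sites <- hap_table_sites(hap_table)
  for (i in seq_len(nrow(hap_table))) {
    if (all(unlist(hap_table[i, sites]) == alleles)) return(hap_table$label[i])
  }
  mint_novel_label(alleles)
}

#' Assign a diplotype to one sample
#'
#' @param dosages named integer vector of allele dosages (0/1/2, `NA`
#'   missing) at the gene's considered sites, in the order of the haplotype
#'   table's site columns.
#' @param hap_table per-gene haplotype table (one element of
#'   [apobec3_haplotype_tables()]); confirmed combinations not in the table
#'   are given deterministic `novel-...` labels encoding the alt-allele
#'   pattern in site order.
#' @param carries_excluded `""` if the sample carries no variant outside the
#'   considered sites, else `"minor_variant"` or `"other"`; a sample that is
#'   reference-homozygous at all considered sites but carries an excluded
#'   variant takes that status instead of `confirmed`.
#' @return list of class `diplotype_call`: `status` (`confirmed`,
#'   `unconfirmed`, `minor_variant`, `other`, `no_call`), `pair` (sorted
#'   label pair or `NA`), `hap1`, `hap2` (allele vectors when confirmed),
#'   `het_count`.
#' @export
assign_diplotype <- function(dosages, hap_table, carries_excluded = "") {
  sites <- hap_table_sites(hap_table)
  dosages <- dosages[sites]
  if (anyNA(dosages)) {
    return(structure(list(status = "no_call", pair = NA_character_,
                          hap1 = NULL, hap2 = NULL,
                          het_count = NA_integer_, dosages = dosages),
                     class = "diplotype_call"))
  }
  het_count <- sum(dosages == 1L)
  if (all(dosages == 0L) && nzchar(carries_excluded)) {
    return(structure(list(status = carries_excluded, pair = NA_character_,
                          hap1 = NULL, hap2 = NULL,
                          het_count = het_count, dosages = dosages),
                     class = "diplotype_call"))
  }
  if (het_count >= 2L) {
    return(structure(list(status = "unconfirmed", pair = NA_character_,
                          hap1 = NULL, hap2 = NULL,
                          het_count = het_count, dosages = dosages),
                     class = "diplotype_call"))
  }
  hap1 <- ifelse(dosages >= 1L, "alt", "ref")
  hap2 <- ifelse(dosages == 2L, "alt", "ref")
  # at the (single) heterozygous site hap1 carries alt, hap2 ref
  names(hap1) <- names(hap2) <- sites
  lab1 <- lookup_hap_label(hap1, hap_table)
  lab2 <- lookup_hap_label(hap2, hap_table)
  ordered <- order_hap_labels(c(lab1, lab2), hap_table)
  structure(list(status = "confirmed",
                 pair = paste(ordered, collapse = "/"),
                 hap1 = hap1, hap2 = hap2, het_count = het_count,
                 dosages = dosages),
            class = "diplotype_call")
}

#' @noRd
order_hap_labels <- function(labels, hap_table) {
  known <- hap_table$label
  rank <- match(labels, known)
  rank[is.na(rank)] <- length(known) + 1L
  labels[order(rank, labels)]
}

#' @export
print.diplotype_call <- function(x, ...) {
  cat(sprintf("diplotype: %s%s (het sites: %s)\n", x$status,
              if (!is.na(x$pair)) paste0(" ", x$pair) else "",
              x$het_count))
  invisible(x)
}

#' Count stable APOBEC3H haplotypes for one sample
#'
#' Stability per haplotype: any haplotype carrying the N15 deletion is
#' unstable; labelled haplotypes take the stability recorded in the table
#' (II stable; I, III, IV unstable; X unstable via the deletion); anything
#' else is unknown. A sample homozygous for the deletion has zero stable
#' haplotypes regardless of phase, so that resolution is applied even to
#' unconfirmed or unassigned calls. Otherwise a non-confirmed call, or a
#' confirmed call involving a haplotype of unknown stability, yields
#' `"unknown"`.
#'
#' @param call a [assign_diplotype()] result for the A3H canonical sites.
#' @param hap_table the A3H haplotype table.
#' @return `"0"`, `"1"`, `"2"` (number of stable haplotypes) or `"unknown"`.
#' @export
classify_a3h_stability <- function(call,
                                   hap_table = apobec3_haplotype_tables()$A3H) {
  if (!"N15del" %in% hap_table_sites(hap_table)) {
    stop_apobec3("stability classification requires the A3H haplotype table")
  }
  del_dosage <- call$dosages[["N15del"]]
  if (!is.na(del_dosage) && del_dosage == 2L) return("0")
  if (call$status != "confirmed") return("unknown")
  stab <- vapply(list(call$hap1, call$hap2), function(h) {
    if (h[["N15del"]] == "alt") return("unstable")
    i <- which(apply(hap_table[, hap_table_sites(hap_table)], 1,
                     function(row) all(row == h)))
    if (length(i) == 1L) hap_table$stability[i] else "unknown"
  }, character(1))
  if (any(stab == "unknown")) return("unknown")
  as.character(sum(stab == "stable"))
}

#' Assign diplotypes across a cohort
#'
#' Runs [assign_diplotype()] for every sample of a gene. Carriage of
#' excluded-site variants (variants of the gene outside the haplotype
#' table's sites) is classified as `"minor_variant"` for previously-reported
#' nonsynonymous variants and `"other"` for synonymous or novel ones,
#' mirroring the published category split; it only affects samples that are
#' reference-homozygous at all considered sites.
#'
#' @param cohort a [cohort_genotypes()] object.
#' @param gene gene identifier.
#' @param hap_table haplotype table; defaults to the shipped table for the
#'   gene.
#' @return data.frame with one row per sample: `sample`, `status`, `pair`,
#'   `het_count`, and for A3H `n_stable` (`"0"`/`"1"`/`"2"`/`"unknown"`).
#' @export
assign_diplotypes <- function(cohort, gene,
                              hap_table = apobec3_haplotype_tables()[[gene]]) {
  if (is.null(hap_table)) stop_apobec3("no haplotype table for gene '", gene, "'")
  sites <- hap_table_sites(hap_table)
  missing_sites <- setdiff(sites, colnames(cohort$geno))
  if (length(missing_sites) > 0) {
    stop_apobec3("cohort lacks considered sites: ",
                 paste(missing_sites, collapse = ", "))
  }
  defs <- cohort$variants
  excl <- defs[defs$gene == gene & !(defs$label %in% sites), , drop = FALSE]
  excl_reason <- if (nrow(excl) > 0) {
    ifelse(excl$effect == "nonsynonymous" & !excl$novel,
           "minor_variant", "other")
  } else character(0)
  rows <- lapply(cohort$samples, function(s) {
    d <- cohort$geno[s, sites]
    carries <- ""
    if (nrow(excl) > 0) {
      carried <- !is.na(cohort$geno[s, excl$label]) &
        cohort$geno[s, excl$label] >= 1L
      if (any(carried)) {
        carries <- if (any(excl_reason[carried] == "minor_variant")) {
          "minor_variant"
        } else {
          "other"
        }
      }
    }
    call <- assign_diplotype(d, hap_table, carries_excluded = carries)
    out <- data.frame(sample = s, status = call$status,
                      pair = call$pair %||% NA_character_,
                      het_count = call$het_count,
                      stringsAsFactors = FALSE)
    if (identical(gene, "A3H")) {
      out$n_stable <- classify_a3h_stability(call, hap_table)
    }
    out
  })
  do.call(rbind, rows)
}

#' Summarize diplotype calls over a cohort
#'
#' Counts and percentages per category (each confirmed pair, plus
#' `unconfirmed`, `minor_variant` and `other`) over the samples with calls
#' (`no_call` rows are excluded from numerator and denominator). For A3H the
#' summary also reports the fraction of samples with zero stable
#' haplotypes.
#'
#' @param calls result of [assign_diplotypes()].
#' @return list of class `cohort_haplotype_summary`: `categories`
#'   (data.frame category/count/pct), `n`, `n_no_call`, and for A3H
#'   `zero_stable` (list with `count` and `pct`).
#' @export
summarize_cohort <- function(calls) {
  stopifnot(nrow(calls) > 0)
  usable <- calls[calls$status != "no_call", , drop = FALSE]
  n <- nrow(usable)
  if (n == 0L) stop_apobec3("no samples with calls")
  category <- ifelse(usable$status == "confirmed", usable$pair, usable$status)
  tab <- table(category)
  cats <- data.frame(category = names(tab), count = as.integer(tab),
                     stringsAsFactors = FALSE)
  cats$pct <- 100 * cats$count / n
  cats <- cats[order(-cats$count, cats$category), , drop = FALSE]
  rownames(cats) <- NULL
  out <- list(categories = cats, n = n,
              n_no_call = nrow(calls) - n)
  if ("n_stable" %in% names(calls)) {
    zero <- sum(usable$n_stable == "0")
    out$zero_stable <- list(count = zero, pct = 100 * zero / n)
  }
  structure(out, class = "cohort_haplotype_summary")
}

#' @export
print.cohort_haplotype_summary <- function(x, ...) {
  cat(sprintf("haplotype summary over n = %d samples (%d without calls)\n",
              x$n, x$n_no_call))
  for (i in seq_len(nrow(x$categories))) {
    cat(sprintf("  %-14s %4d (%.1f%%)\n", x$categories$category[i],
                x$categories$count[i], round_half_up(x$categories$pct[i], 1)))
  }
  if (!is.null(x$zero_stable)) {
    cat(sprintf("  zero stable haplotypes: %d (%.1f%%)\n",
                x$zero_stable$count, round_half_up(x$zero_stable$pct, 1)))
  }
  invisible(x)
}
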