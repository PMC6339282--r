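# End-to-end orchestration: ingest -> annotate -> per-variant statistics ->
# population comparison -> LD -> haplotype summary, written as a bundle of
# TSV reports plus a JSON run manifest. Report rounding is centralized here
# (half away from zero); everything upstream stays at full precision.

#' Run configuration for the full report
#'
#' @param genotypes path to a genotype TSV (see [read_genotype_table()]), or
#'   `NULL` to analyse the packaged fixture cohorts.
#' @param out_dir output directory (created if needed).
#' @param maf_pct haplotype site-frequency threshold (percent).
#' @param alpha significance threshold for HWE deviation and population
#'   comparisons.
#' @param ld_report_cutoff R-squared above which an LD pair is flagged.
#' @param seed integer seed recorded in the manifest (the report itself is
#'   deterministic).
#' @return list of class `run_config`.
#' @export
run_config <- function(genotypes = NULL, out_dir = "results",
                       maf_pct = 5, alpha = 0.05, ld_report_cutoff = 0.1,
                       seed = 1L) {
  stopifnot(maf_pct > 0, maf_pct <= 50, alpha > 0, alpha < 1,
            ld_report_cutoff >= 0, ld_report_cutoff <= 1)
  if (!is.null(genotypes) && !file.exists(genotypes)) {
    stop_apobec3("genotype file not found: ", genotypes)
  }
  structure(list(genotypes = genotypes, out_dir = out_dir, maf_pct = maf_pct,
                 alpha = alpha, ld_report_cutoff = ld_report_cutoff,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file whose keys mirror the arguments of [run_config()].
#' @return list of class `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' @noRd
round_report <- function(df, pct_cols = character(), stat_cols = character()) {
  for (col in intersect(pct_cols, names(df))) {
    df[[col]] <- round_half_up(df[[col]], 1)
  }
  for (col in intersect(stat_cols, names(df))) {
    df[[col]] <- round_half_up(df[[col]], 3)
  }
  df
}

#' @noRd
write_report_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full APOBEC3 characterization report
#'
#' Produces, under `config$out_dir`: per-variant annotation + genotype
#' counts + frequencies + HWE (`variants_hwe.tsv`), reference-population
#' comparisons (`population_comparison.tsv`), per-gene pairwise LD
#' (`ld_<gene>.tsv`), per-gene diplotype calls and haplotype summaries
#' (`diplotypes_<gene>.tsv`, `haplotype_summary.tsv`), and a JSON manifest
#' (`manifest.json`) recording parameters and package version. Rerunning
#' with the same inputs reproduces the outputs byte-identically (the
#' manifest's timestamp excepted).
#'
#' @param config a [run_config()].
#' @param cohorts optional named list of [cohort_genotypes()] per gene,
#'   overriding `config$genotypes`; defaults to the packaged
#'   genotype-count fixtures, with the haplotype-category fixtures used for
#'   the diplotype summaries (see [fixture_from_printed_tables()]).
#' @return named list of written paths, invisibly.
#' @export
run_apobec3_report <- function(config = run_config(), cohorts = NULL) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hap_cohorts <- NULL
  if (is.null(cohorts)) {
    if (!is.null(config$genotypes)) {
      full <- read_genotype_table(config$genotypes)
      cohorts <- split_by_gene(full)
      hap_cohorts <- cohorts
    } else {
      cohorts <- fixture_from_printed_tables("genotype_counts")
      hap_cohorts <- fixture_from_printed_tables("haplotype_categories")
    }
  } else {
    hap_cohorts <- cohorts
  }
  if (length(cohorts) == 0L ||
      all(vapply(cohorts, function(cc) length(cc$samples) == 0L, logical(1)))) {
    stop_apobec3("empty cohort: nothing to analyse")
  }
  paths <- list()

  ann <- annotate_variant_table(
    do.call(rbind, lapply(cohorts, function(cc) cc$variants)))
  hwe <- do.call(rbind, lapply(cohorts, hwe_table, alpha = config$alpha))
  variants_hwe <- merge(ann, hwe,
                        by = c("gene", "label", "variant_id"), sort = FALSE)
  variants_hwe <- variants_hwe[order(variants_hwe$gene, variants_hwe$cds_pos), ]
  variants_hwe <- round_report(variants_hwe,
                               pct_cols = c("ref_pct", "alt_pct", "maf_pct"),
                               stat_cols = c("chi2"))
  paths$variants_hwe <- write_report_tsv(
    variants_hwe, file.path(config$out_dir, "variants_hwe.tsv"))

  cmp <- do.call(rbind, lapply(cohorts, comparison_table, alpha = config$alpha))
  if (!is.null(cmp)) {
    rownames(cmp) <- NULL
    paths$population_comparison <- write_report_tsv(
      cmp, file.path(config$out_dir, "population_comparison.tsv"))
  }

  for (g in names(cohorts)) {
    poly <- sum(vapply(cohorts[[g]]$variants$label, function(lab) {
      d <- cohorts[[g]]$geno[, lab]
      length(unique(stats::na.omit(d))) > 1L
    }, logical(1)))
    if (poly < 2L) next
    ld <- ld_matrix(cohorts[[g]], g)
    ld$pairs$flagged <- ld$pairs$R2 > config$ld_report_cutoff
    paths[[paste0("ld_", g)]] <- write_report_tsv(
      ld$pairs, file.path(config$out_dir, paste0("ld_", g, ".tsv")))
  }

  summaries <- list()
  hap_tables <- apobec3_haplotype_tables()
  for (g in names(hap_cohorts)) {
    if (!g %in% names(hap_tables)) next
    calls <- assign_diplotypes(hap_cohorts[[g]], g)
    paths[[paste0("diplotypes_", g)]] <- write_report_tsv(
      calls, file.path(config$out_dir, paste0("diplotypes_", g, ".tsv")))
    s <- summarize_cohort(calls)
    cats <- round_report(s$categories, pct_cols = "pct")
    cats <- cbind(gene = g, cats, n = s$n, stringsAsFactors = FALSE)
    if (!is.null(s$zero_stable)) {
      cats <- rbind(cats, data.frame(
        gene = g, category = "zero_stable_haplotypes",
        count = s$zero_stable$count,
        pct = round_half_up(s$zero_stable$pct, 1), n = s$n,
        stringsAsFactors = FALSE))
    }
    summaries[[g]] <- cats
  }
  if (length(summaries) > 0) {
    paths$haplotype_summary <- write_report_tsv(
      do.call(rbind, summaries),
      file.path(config$out_dir, "haplotype_summary.tsv"))
  }

  manifest <- list(
    package = "apobec3pop",
    version = as.character(utils::packageVersion("apobec3pop")),
    parameters = list(maf_pct = config$maf_pct, alpha = config$alpha,
                      ld_report_cutoff = config$ld_report_cutoff,
                      seed = config$seed),
    inputs = if (is.null(config$genotypes)) "packaged fixtures" else config$genotypes,
    outputs = unname(unlist(paths)),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  paths$manifest <- manifest_path
  invisible(paths)
}

#' Split a multi-gene cohort into per-gene cohorts
#'
#' @param cohort a [cohort_genotypes()] object.
#' @return named list of per-gene [cohort_genotypes()].
#' @export
split_by_gene <- function(cohort) {
  genes <- unique(cohort$variants$gene)
  out <- lapply(genes, function(g) {
    keep <- cohort$variants$gene == g
    cohort_genotypes(cohort$samples, cohort$variants[keep, , drop = FALSE],
                     cohort$geno[, cohort$variants$label[keep], drop = FALSE])
  })
  names(out) <- genes
  out
}
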