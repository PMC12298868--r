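#' Assemble a run configuration for the full pipeline
#'
#' Bundles simulation configs (or input file paths), strategy-grid factors,
#' filtering and verdict thresholds, sampling ratios and seeds. Every
#' threshold is recorded in the run manifest.
#'
#' @param pheno pheno_sim_config, or path to a trait CSV.
#' @param geno geno_sim_config, or path to a VCF/HapMap file (see
#'   \code{geno_format}).
#' @param stress stress_sim_config, or path to an indicator CSV.
#' @param geno_format file format when \code{geno} is a path.
#' @param distances,ratios,allocations,linkages strategy-grid factors.
#' @param geno_ratio genotypic core sampling ratio (default 0.15).
#' @param alpha significance level for MD/VD tests.
#' @param maf_min,pms_max SNP filter thresholds.
#' @param md_max,cr_min verdict thresholds.
#' @param k_true slope-change K for the synthetic likelihood table.
#' @param weights comprehensive-D weighting scheme.
#' @param seed master seed; stage seeds derive from it.
#' @return list of class \code{run_config}.
#' @export
run_config <- function(pheno = NULL, geno = NULL, stress = NULL,
                       geno_format = "vcf",
                       distances = c("euclidean", "mahalanobis"),
                       ratios = c(0.1, 0.15, 0.2, 0.25, 0.3),
                       allocations = c("random", "deviation"),
                       linkages = c("flexible", "ward"),
                       geno_ratio = 0.15, alpha = 0.05,
                       maf_min = 0.01, pms_max = 0.01,
                       md_max = 20, cr_min = 80, k_true = 6,
                       weights = "pca_contribution", seed = 1L) {
  stopifnot(alpha > 0, alpha < 1, maf_min >= 0, pms_max <= 1,
            geno_ratio > 0, geno_ratio <= 1)
  seed <- as.integer(seed)
  if (is.null(pheno)) pheno <- pheno_sim_config(seed = seed)
  if (is.null(geno)) geno <- geno_sim_config(seed = seed + 1L)
  structure(list(pheno = pheno, geno = geno, stress = stress,
                 geno_format = geno_format, distances = distances,
                 ratios = ratios, allocations = allocations,
                 linkages = linkages, geno_ratio = geno_ratio,
                 alpha = alpha, maf_min = maf_min, pms_max = pms_max,
                 md_max = md_max, cr_min = cr_min, k_true = k_true,
                 weights = weights, seed = seed),
            class = "run_config")
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run the full core-collection pipeline
#'
#' Stages, in dependency order: load or simulate inputs; trait summaries,
#' correlations and PCA; strategy-grid phenotypic core sampling with
#' MD/VD/CR/VR evaluation and ranking; SNP filtering, diversity statistics,
#' GSC, SNP density, genotype PCA and Evanno delta-K; genotypic core
#' selection; core integration; membership-function salt-alkali
#' classification of the integrated core. All tabular artifacts are written
#' under \code{out_dir} together with a JSON manifest recording inputs,
#' parameters and seeds; a rerun with the same config reproduces identical
#' outputs.
#'
#' @param config run_config.
#' @param out_dir output directory (created if needed); NULL skips writing.
#' @return list with every stage result and the manifest.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  # --- inputs -------------------------------------------------------------
  tm <- if (inherits(config$pheno, "pheno_sim_config"))
    simulate_phenotypes(config$pheno) else read_traits(config$pheno)
  g <- if (inherits(config$geno, "geno_sim_config"))
    simulate_genotypes(config$geno)
  else read_genotypes(config$geno, config$geno_format)
  # --- phenotypic diversity ----------------------------------------------
  summary_tab <- summarize_traits(tm)
  corr <- correlate_traits(tm)
  pca <- pca_traits(tm)
  # --- phenotypic core grid ----------------------------------------------
  cores <- strategy_grid(tm, config$distances, config$ratios,
                         config$allocations, config$linkages,
                         seed = config$seed)
  evals <- lapply(cores, function(cs)
    evaluate_core(subset_accessions(tm, cs$selected), tm,
                  alpha = config$alpha, md_max = config$md_max,
                  cr_min = config$cr_min))
  ranking <- rank_strategies(evals)
  best <- cores[[ranking$strategy[1L]]]
  pca_cmp <- compare_pca(subset_accessions(tm, best$selected), tm)
  # --- genotypic diversity -----------------------------------------------
  gf <- filter_loci(g, config$maf_min, config$pms_max)
  div <- diversity_stats(gf)
  gsc <- gsc_matrix(gf)
  density <- snp_density(gf)
  gpca <- genotype_pca(gf)
  ktab <- simulate_structure_likelihoods(true_k = config$k_true,
                                         seed = config$seed + 2L)
  deltak <- evanno_delta_k(ktab)
  # --- genotypic core and integration ------------------------------------
  geno_core <- select_geno_core(gf, config$geno_ratio)
  integrated <- integrate_cores(best$selected, geno_core$selected,
                                rownames(tm$values))
  # --- salt-alkali classification of the integrated core ------------------
  stress_cfg <- config$stress
  if (is.null(stress_cfg))
    stress_cfg <- stress_sim_config(n_accessions = length(integrated$final),
                                    seed = config$seed + 3L)
  germ <- if (inherits(stress_cfg, "stress_sim_config")) {
    sim <- simulate_germination(stress_cfg)
    sim$indicators
  } else read_traits(stress_cfg)
  U <- membership(germ)
  dvals <- comprehensive_d(U, config$weights)
  groups <- classify_tolerance(dvals$d)
  manifest <- list(
    package_version = as.character(utils::packageVersion("germcore")),
    seed = config$seed,
    parameters = config[c("distances", "ratios", "allocations", "linkages",
                          "geno_ratio", "alpha", "maf_min", "pms_max",
                          "md_max", "cr_min", "k_true", "weights")],
    n_accessions = nrow(tm$values),
    n_loci_input = ncol(g$calls),
    n_loci_filtered = ncol(gf$calls),
    best_strategy = ranking$strategy[1L],
    core_sizes = as.list(integrated$counts),
    best_k = deltak$best_k,
    tolerant_count = length(groups$tolerant_ids))
  result <- list(traits = tm, genotypes = g, summary = summary_tab,
                 correlation = corr, pca = pca, cores = cores,
                 evaluations = evals, ranking = ranking,
                 best_core = best, pca_comparison = pca_cmp,
                 genotypes_filtered = gf, diversity = div, gsc = gsc,
                 snp_density = density, genotype_pca = gpca,
                 k_table = ktab, delta_k = deltak, geno_core = geno_core,
                 integrated = integrated, membership = U, d_values = dvals,
                 tolerance = groups, manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(out_dir, f)
    write_traits(tm, p("traits.csv"))
    utils::write.csv(summary_tab, p("trait_summary.csv"), row.names = FALSE)
    utils::write.csv(round(corr$r, 6), p("trait_correlation.csv"))
    utils::write.csv(ranking, p("strategy_ranking.csv"), row.names = FALSE)
    writeLines(best$selected, p("pheno_core_ids.csv"))
    utils::write.csv(div$per_locus, p("locus_stats.csv"), row.names = FALSE)
    utils::write.csv(round(gsc, 6), p("gsc_matrix.csv"))
    utils::write.csv(density$per_chrom, p("snp_per_chrom.csv"),
                     row.names = FALSE)
    utils::write.table(ktab, p("k_run_table.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    utils::write.csv(deltak$table, p("delta_k.csv"), row.names = FALSE)
    writeLines(geno_core$selected, p("geno_core_ids.csv"))
    writeLines(integrated$final, p("integrated_core_ids.csv"))
    writeLines(integrated$reserve, p("reserve_ids.csv"))
    utils::write.csv(data.frame(accession = names(dvals$d),
                                d = dvals$d,
                                group = as.character(groups$group),
                                tolerance = groups$tolerance),
                     p("tolerance_groups.csv"), row.names = FALSE)
    write_json_file(manifest, p("manifest.json"))
  }
  result
}
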