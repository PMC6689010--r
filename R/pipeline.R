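# End-to-end orchestration on synthetic data: generate a strain panel and
# case/control cohorts with planted truth, then run preprocessing, module
# inference, trait association, conservation, differential co-expression,
# network-eQTL mapping, syntenic translation and regulator profiling, and
# check every planted signal was recovered.

#' Pipeline configuration with paper-default parameters
#'
#' Unknown keys in `overrides` are rejected. Defaults: FPKM threshold 1 in
#' at least 5% of samples, outlier cut at the 0.99 height quantile,
#' module merge height 0.25, GSEA 10000 permutations (min size 10, max
#' 5000), dispersion test 100000 permutations, E(p_g) = 2, median-BF call
#' threshold 100, syntenic window 10 Mb, core-set FDR 0.01.
#'
#' @param overrides Named list of values to override.
#' @return Named list of resolved parameters.
#' @export
pipeline_config <- function(overrides = list()) {
  cfg <- list(fpkm_threshold = 1, min_frac = 0.05, height_quantile = 0.99,
              merge_height = 0.25, min_module_size = 30,
              gsea_n_perm = 10000, gsea_min_size = 10, gsea_max_size = 5000,
              diffcoex_n_perm = 100000, e_pg = 2, bf_threshold = 100,
              window_mb = 10, core_fdr = 0.01, assoc_fdr = 0.05,
              n_iter = 10000, seed = 1)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  cfg[names(overrides)] <- overrides
  cfg
}

#' Deterministic per-stage seed
#'
#' Derives a stage seed from the global seed by hashing the stage name,
#' so stages can be rerun independently yet reproducibly. Always below
#' 2^31.
#'
#' @param seed Global integer seed.
#' @param stage Stage name.
#' @return Integer seed.
#' @export
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_len(nchar(stage)))
  as.integer((abs(as.numeric(seed)) * 977 + h * 131) %% 2147483647)
}

#' Run the bundled synthetic demonstration end-to-end
#'
#' Generates a recombinant-inbred-style panel with a planted hotspot
#' module and fibrosis-like traits, plus case/control cohorts with a
#' planted differentially co-expressed module and a planted regulator
#' gene; then runs every analysis stage and checks planted-truth
#' recovery. All outputs (TSV matrices, GMT module sets, BED intervals,
#' JSON truth/config/report) are written under `outdir`.
#'
#' @param outdir Writable output directory (created if absent).
#' @param seed Global integer seed; per-stage seeds derive from it.
#' @param config Optional overrides for [pipeline_config()]. The demo
#'   scales permutation counts down (GSEA 1000, dispersion 2000, sampler
#'   2000 iterations) to run in seconds; pass overrides to change that.
#' @param strict Stop with an error if a planted signal is not recovered
#'   (default TRUE).
#' @return The report, invisibly: a list with module-recovery, trait
#'   association, conservation, differential co-expression, locus-call
#'   and core-set summaries.
#' @export
run_demo <- function(outdir, seed = 1, config = list(), strict = TRUE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cfg <- pipeline_config(utils::modifyList(
    list(gsea_n_perm = 1000, diffcoex_n_perm = 2000, n_iter = 2000,
         seed = seed), config))
  report <- list(seed = seed)

  ## --- synthetic panel with hotspot -------------------------------------
  geno <- generate_genotypes(n_strains = 30, n_blocks = 50,
                             snps_per_block = 2,
                             seed = stage_seed(seed, "genotypes"))
  panel <- generate_panel_expression(geno, n_genes = 150,
                                     module_sizes = c(40, 30),
                                     hotspot_block = "B7",
                                     seed = stage_seed(seed, "panel"))
  ph <- generate_phenotype(panel$expr, panel$truth,
                           seed = stage_seed(seed, "phenotype"))
  write_genotype_tsv(geno, file.path(outdir, "genotypes.tsv"))
  write_expression_tsv(panel$expr, file.path(outdir, "panel_expression.tsv"))
  write_phenotype_tsv(ph$pheno, file.path(outdir, "phenotypes.tsv"))
  write_truth_json(ph$truth, file.path(outdir, "panel_truth.json"))

  ## --- preprocessing ----------------------------------------------------
  pheno <- ph$pheno
  for (tr in names(pheno$traits))
    pheno <- adjust_trait_for_covariate(pheno, tr, "mean_bp")

  ## --- module inference on the panel ------------------------------------
  inf <- infer_modules(panel$expr, beta = NULL, candidate_betas = 1:12,
                       min_size = cfg$min_module_size,
                       merge_height = cfg$merge_height)
  modules <- inf$modules
  write_gmt(modules_as_gene_sets(modules), file.path(outdir, "modules.gmt"))
  truth_labels <- ph$truth$module_assignments[names(modules$assignments)]
  recovered <- vapply(c("P1", "P2"), function(pl) {
    planted <- names(truth_labels)[truth_labels == pl]
    tab <- table(modules$assignments[planted])
    tab <- tab[names(tab) != "unassigned"]
    if (!length(tab)) return(NA_character_)
    best <- names(tab)[which.max(tab)]
    if (tab[best] / length(planted) >= 0.9) best else NA_character_
  }, "")
  report$modules <- list(n_detected = length(modules$module_order),
                         beta = inf$beta,
                         planted_recovered_as = as.list(recovered))

  ## --- trait association (pre-ranked GSEA) ------------------------------
  assoc <- associate_modules(modules, panel$expr, pheno,
                             traits = names(pheno$traits),
                             n_perm = cfg$gsea_n_perm,
                             min_size = cfg$gsea_min_size,
                             max_size = cfg$gsea_max_size,
                             seed = stage_seed(seed, "gsea"),
                             fdr_cut = cfg$assoc_fdr)
  report$trait_association <- lapply(assoc, function(res)
    list(associated_modules = res$set[res$associated],
         nes = stats::setNames(round(res$nes, 3), res$set)))

  ## --- case/control cohorts with planted regulator ----------------------
  cc <- generate_case_control(n_cases = 100, n_controls = 100,
                              module_sizes = 40, corr_cases = 0.8,
                              corr_controls = 0.1, n_background = 110,
                              regulator_loading_cases = 0.6,
                              seed = stage_seed(seed, "cohorts"))
  write_expression_tsv(cc$cases, file.path(outdir, "cases_expression.tsv"))
  write_expression_tsv(cc$controls, file.path(outdir, "controls_expression.tsv"))
  write_truth_json(cc$truth, file.path(outdir, "cohort_truth.json"))
  # dendrogram sample QC on the cohorts (as in the human processing)
  qc_cases <- remove_outlier_samples(cc$cases, cfg$height_quantile)
  qc_controls <- remove_outlier_samples(cc$controls, cfg$height_quantile)
  report$outlier_samples_removed <- c(qc_cases$removed, qc_controls$removed)
  hmods <- infer_modules(qc_cases$expr, beta = NULL, candidate_betas = 1:12,
                         min_size = cfg$min_module_size,
                         merge_height = cfg$merge_height)$modules

  ## --- cross-species conservation ---------------------------------------
  shared <- intersect(gene_ids(panel$expr), gene_ids(cc$cases))
  omap <- ortholog_map(paste0("rn_", shared), paste0("hs_", shared))
  mod_a <- module_set(stats::setNames(modules$assignments,
                                      paste0("rn_", names(modules$assignments))))
  mod_b <- module_set(stats::setNames(hmods$assignments,
                                      paste0("hs_", names(hmods$assignments))))
  bg <- build_background(omap, paste0("rn_", gene_ids(panel$expr)),
                         paste0("hs_", gene_ids(cc$cases)))
  cons <- conservation_test(mod_a, mod_b, bg)
  best_pair <- cons[which.min(cons$adjusted_p), ]
  report$conservation <- list(n_tests = nrow(cons),
                              best_pair = paste(best_pair$module_a,
                                                best_pair$module_b),
                              overlap = best_pair$overlap,
                              adjusted_p = best_pair$adjusted_p)

  ## --- differential co-expression ---------------------------------------
  hsets <- modules_as_gene_sets(hmods)
  cache <- diffcoex_correlations(qc_cases$expr, qc_controls$expr)
  dc <- lapply(hsets, function(g)
    differential_coexpression_test(qc_cases$expr, qc_controls$expr, g,
                                   n_perm = cfg$diffcoex_n_perm,
                                   seed = stage_seed(seed, "diffcoex"),
                                   n_modules_tested = length(hsets),
                                   corr_cache = cache))
  report$differential_coexpression <- lapply(dc, function(r)
    list(dispersion = r$dispersion, empirical_p = r$empirical_p,
         bonferroni_p = r$bonferroni_p))

  ## --- network-eQTL mapping ----------------------------------------------
  pruned <- prune_ld_blocks(geno)
  target <- recovered[["P1"]]
  map_genes <- if (!is.na(target)) module_genes(modules, target) else
    names(truth_labels)[truth_labels == "P1"]
  nq <- network_eqtl_map(panel$expr, map_genes, pruned, e_pg = cfg$e_pg,
                         n_iter = cfg$n_iter,
                         seed = stage_seed(seed, "eqtl"),
                         bf_threshold = cfg$bf_threshold)
  called <- nq$summary[nq$summary$called, ]
  report$network_eqtl <- list(
    prior_pi = nq$prior_pi,
    called_snps = called$snp_id,
    hotspot_snp = ph$truth$hotspot_snp,
    hotspot_block = pruned$block_id[match(ph$truth$hotspot_snp,
                                          rownames(pruned$dosage))],
    max_median_bf = max(nq$summary$median_bf))
  utils::write.table(nq$summary, file.path(outdir, "locus_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## --- syntenic window ----------------------------------------------------
  if (nrow(called)) {
    top <- called[which.max(called$median_bf), ]
    blk_snps <- which(geno$block_id ==
                        geno$block_id[match(top$snp_id, rownames(geno$dosage))])
    block_iv <- genomic_interval(top$chrom, min(geno$pos[blk_snps]),
                                 max(geno$pos[blk_snps]))
    center <- block_iv$start + (block_iv$end - block_iv$start) / 2
    genes_src <- data.frame(gene_id = "anchor_rn", chrom = block_iv$chrom,
                            start = center - 5000, end = center + 5000)
    genes_tgt <- data.frame(gene_id = "anchor_hs", chrom = "chr16",
                            start = 69360969, end = 69470969)
    win <- syntenic_window(block_iv, genes_src,
                           ortholog_map("anchor_rn", "anchor_hs"),
                           genes_tgt, window_mb = cfg$window_mb)
    write_bed(list(syntenic_window = win),
              file.path(outdir, "syntenic_window.bed"))
    report$syntenic_window <- sprintf("%s:%.0f..%.0f", win$chrom,
                                      win$start, win$end)
  } else {
    report$syntenic_window <- "no locus called"
  }

  ## --- regulator profiling -----------------------------------------------
  cc2 <- generate_case_control(n_cases = 60, n_controls = 60,
                               module_sizes = 40, corr_cases = 0.8,
                               corr_controls = 0.1, n_background = 110,
                               regulator_loading_cases = 0.6,
                               seed = stage_seed(seed, "cohorts2"))
  mg <- names(cc$truth$module_assignments)[cc$truth$module_assignments == "P1"]
  prof_cases <- regulator_correlations(cc$cases, "regulator", mg)
  prof_ctrl <- regulator_correlations(cc$controls, "regulator", mg)
  prof_cases2 <- regulator_correlations(cc2$cases, "regulator", mg)
  sh <- shift_test(prof_cases, prof_ctrl)
  core <- core_set(list(cohort1 = prof_cases, cohort2 = prof_cases2),
                   fdr_threshold = cfg$core_fdr)
  writeLines(core, file.path(outdir, "core_set.txt"))
  report$regulator <- list(shift_p = sh$p, shift_direction = sh$direction,
                           median_rho_cases = stats::median(prof_cases$rho),
                           median_rho_controls = stats::median(prof_ctrl$rho),
                           core_set_size = length(core))

  ## --- planted-truth checks ----------------------------------------------
  checks <- c(
    both_planted_modules_recovered = all(!is.na(recovered)),
    hotspot_module_trait_associated =
      !is.na(target) && all(vapply(assoc, function(res)
        target %in% res$set[res$associated], TRUE)),
    planted_cohort_module_conserved = best_pair$adjusted_p < 0.05,
    differential_coexpression_detected =
      any(vapply(dc, function(r) r$bonferroni_p < 0.05, TRUE)),
    hotspot_locus_called = !is.na(ph$truth$hotspot_snp) &&
      report$network_eqtl$hotspot_block %in%
        pruned$block_id[match(called$snp_id, rownames(pruned$dosage))],
    regulator_shift_positive = sh$p < 0.05 && sh$direction > 0,
    core_set_nonempty = length(core) > 0)
  report$checks <- as.list(checks)
  report$all_checks_passed <- all(checks)

  jsonlite::write_json(cfg, file.path(outdir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (strict && !all(checks))
    stop("planted-truth recovery failed: ",
         paste(names(checks)[!checks], collapse = ", "))
  invisible(report)
}
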