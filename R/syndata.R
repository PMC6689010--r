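# Synthetic data with planted ground truth. The generators emulate the
# statistical structure the downstream analyses assume: an RI-like strain
# panel with LD-blocked binary genotypes and one trans-acting hotspot
# driving a gene module; case/control cohorts where a planted module is
# co-expressed in cases and decorrelated in controls; and fibrosis-like
# traits loaded on the module eigengene with a blood-pressure-like
# confounder. Expression is generated at the already-normalized matrix
# level; reads, isoforms and library-size effects are not simulated.

#' Planted-truth record
#'
#' @param module_assignments Named character vector gene id -> planted label
#'   (`"background"` for genes outside any module).
#' @param hotspot_snp Id of the planted hotspot SNP (or `NA`).
#' @param hotspot_effect Per-allele shift added to the hotspot module's
#'   latent factor, in factor SD units.
#' @param module_corr_cases,module_corr_controls Planted equicorrelation of
#'   module genes in the two cohorts, in `[0, 1]`.
#' @param trait_loading,confounder_loading Loadings of the fibrosis-like
#'   traits on the module eigengene and the BP-like covariate.
#' @param seed Seed the data were generated under.
#' @return An object of class `SyntheticTruth`.
#' @export
synthetic_truth <- function(module_assignments, hotspot_snp = NA_character_,
                            hotspot_effect = 0, module_corr_cases = NA_real_,
                            module_corr_controls = NA_real_,
                            trait_loading = NA_real_,
                            confounder_loading = NA_real_, seed = NA_integer_) {
  if (!is.na(module_corr_cases) && !is.na(module_corr_controls) &&
      module_corr_cases < module_corr_controls)
    stop("module_corr_cases must be >= module_corr_controls")
  structure(list(module_assignments = module_assignments,
                 hotspot_snp = hotspot_snp, hotspot_effect = hotspot_effect,
                 module_corr_cases = module_corr_cases,
                 module_corr_controls = module_corr_controls,
                 trait_loading = trait_loading,
                 confounder_loading = confounder_loading, seed = seed),
            class = "SyntheticTruth")
}

#' Generate an RI-style genotype panel
#'
#' Binary two-founder genotypes in LD blocks: all SNPs within a block share
#' one strain-distribution pattern, so a block is genetically a single
#' marker. Each block's pattern is drawn with minor-allele frequency in
#' `[0.2, 0.5]`. Blocks are tiled every 50 kb, 100 blocks per synthetic
#' chromosome, SNPs 100 bp apart within a block (1-based positions).
#'
#' @param n_strains Number of strains (samples).
#' @param n_blocks Number of LD blocks.
#' @param snps_per_block SNPs per block.
#' @param seed Integer seed; identical arguments reproduce the matrix.
#' @return A `GenotypeMatrix` with `block_id` set to `B1..Bn_blocks`.
#' @export
generate_genotypes <- function(n_strains, n_blocks, snps_per_block, seed) {
  if (n_strains < 1 || n_blocks < 1 || snps_per_block < 1)
    stop("all counts must be >= 1")
  set.seed(seed)
  lo <- max(1L, ceiling(0.2 * n_strains))
  hi <- max(lo, floor(0.5 * n_strains))
  p <- n_blocks * snps_per_block
  dosage <- matrix(0, p, n_strains)
  chrom <- character(p); pos <- integer(p); block <- character(p)
  for (b in seq_len(n_blocks)) {
    m <- if (lo == hi) lo else sample(lo:hi, 1)
    pattern <- integer(n_strains)
    pattern[sample.int(n_strains, m)] <- 1L
    idx <- (b - 1L) * snps_per_block + seq_len(snps_per_block)
    dosage[idx, ] <- matrix(pattern, snps_per_block, n_strains, byrow = TRUE)
    b0 <- (b - 1L) %% 100L          # block index within its chromosome
    chrom[idx] <- paste0("chr", (b - 1L) %/% 100L + 1L)
    pos[idx] <- b0 * 50000L + 1L + (seq_len(snps_per_block) - 1L) * 100L
    block[idx] <- paste0("B", b)
  }
  rownames(dosage) <- sprintf("snp%04d", seq_len(p))
  colnames(dosage) <- sprintf("strain%02d", seq_len(n_strains))
  genotype_matrix(dosage, chrom, pos, block, ploidy = "inbred")
}

#' Generate panel expression with a planted hotspot module
#'
#' Each module `m` has a latent factor `f_m ~ N(0, 1)` across strains; the
#' hotspot module's factor additionally gains `effect x dosage` of the
#' hotspot block's strain-distribution pattern. Gene `g` of module `m` is
#' `lambda_g * f_m + eps`, with loadings drawn uniformly in `[0.4, 0.9]`
#' (co-expressed but not collinear) and `eps ~ N(0, noise_sd^2)`. Genes
#' outside all modules are independent `N(0, 1)` noise.
#'
#' @param genotypes A `GenotypeMatrix` from [generate_genotypes()].
#' @param n_genes Total number of genes.
#' @param module_sizes Integer vector of planted module sizes (labels
#'   `P1..Pk`); their sum must not exceed `n_genes`.
#' @param hotspot_block Block id carrying the hotspot (its first SNP is
#'   recorded as the hotspot SNP); the hotspot drives module `P1`.
#' @param hotspot_effect Per-allele factor shift (default 3; see the
#'   methods vignette for the power analysis behind the default).
#' @param noise_sd Gene-level noise SD (default 0.3).
#' @param seed Integer seed.
#' @return List with elements `expr` (an `ExpressionMatrix`, unit
#'   `"log2"`) and `truth` (a `SyntheticTruth`).
#' @export
generate_panel_expression <- function(genotypes, n_genes, module_sizes,
                                      hotspot_block = NULL,
                                      hotspot_effect = 3, noise_sd = 0.3,
                                      seed = 1) {
  if (sum(module_sizes) > n_genes)
    stop("sum of module_sizes exceeds n_genes")
  n <- ncol(genotypes$dosage)
  hotspot_snp <- NA_character_
  hot_dosage <- numeric(n)
  if (!is.null(hotspot_block) && hotspot_effect != 0) {
    in_block <- which(genotypes$block_id == hotspot_block)
    if (!length(in_block)) stop("hotspot block ", hotspot_block, " not found")
    hotspot_snp <- rownames(genotypes$dosage)[in_block[1]]
    hot_dosage <- genotypes$dosage[in_block[1], ]
  }
  set.seed(seed)
  values <- matrix(stats::rnorm(n_genes * n), n_genes, n)
  labels <- rep("background", n_genes)
  g0 <- 0L
  for (m in seq_along(module_sizes)) {
    sz <- module_sizes[m]
    f <- stats::rnorm(n)
    if (m == 1L) f <- f + hotspot_effect * hot_dosage
    lambda <- stats::runif(sz, 0.4, 0.9)
    idx <- g0 + seq_len(sz)
    values[idx, ] <- lambda %o% f +
      matrix(stats::rnorm(sz * n, sd = noise_sd), sz, n)
    labels[idx] <- paste0("P", m)
    g0 <- g0 + sz
  }
  rownames(values) <- sprintf("gene%04d", seq_len(n_genes))
  colnames(values) <- colnames(genotypes$dosage)
  truth <- synthetic_truth(stats::setNames(labels, rownames(values)),
                           hotspot_snp = hotspot_snp,
                           hotspot_effect = hotspot_effect, seed = seed)
  list(expr = expression_matrix(values, unit = "log2"), truth = truth)
}

#' Generate case/control cohorts with planted differential co-expression
#'
#' Module genes are equicorrelated by a single-factor construction,
#' `gene = sqrt(rho) * f + sqrt(1 - rho) * eps`, with pairwise correlation
#' `corr_cases` in the case matrix and `corr_controls` in the control
#' matrix; background genes are independent `N(0, 1)`. Both matrices share
#' the same gene ids. Optionally a regulator gene (`"regulator"`) is
#' emitted that loads on the first module's factor in each cohort.
#'
#' @param n_cases,n_controls Cohort sizes (both >= 1).
#' @param module_sizes Integer vector of planted module sizes.
#' @param corr_cases,corr_controls Planted pairwise correlations, with
#'   `0 <= corr_controls <= corr_cases <= 1`.
#' @param n_background Number of independent background genes.
#' @param regulator_loading_cases,regulator_loading_controls Squared-
#'   correlation loadings of the regulator gene on the first module factor
#'   (0 to omit the signal; the gene is emitted only when either is > 0).
#' @param seed Integer seed.
#' @return List with `cases` and `controls` (`ExpressionMatrix`, unit
#'   `"log2"`) and `truth` (a `SyntheticTruth`).
#' @export
generate_case_control <- function(n_cases, n_controls, module_sizes,
                                  corr_cases, corr_controls, n_background,
                                  regulator_loading_cases = 0,
                                  regulator_loading_controls = 0, seed = 1) {
  if (n_cases < 1 || n_controls < 1) stop("cohort sizes must be >= 1")
  if (corr_controls < 0 || corr_cases > 1 || corr_cases < corr_controls)
    stop("need 0 <= corr_controls <= corr_cases <= 1")
  set.seed(seed)
  n_genes <- sum(module_sizes) + n_background
  gene_names <- sprintf("gene%04d", seq_len(n_genes))
  labels <- rep("background", n_genes)
  g0 <- 0L
  for (m in seq_along(module_sizes)) {
    labels[g0 + seq_len(module_sizes[m])] <- paste0("P", m)
    g0 <- g0 + module_sizes[m]
  }
  with_reg <- regulator_loading_cases > 0 || regulator_loading_controls > 0

  cohort <- function(n, rho, reg_rho, prefix) {
    values <- matrix(stats::rnorm(n_genes * n), n_genes, n)
    g0 <- 0L
    f1 <- NULL
    for (m in seq_along(module_sizes)) {
      f <- stats::rnorm(n)
      if (m == 1L) f1 <- f
      idx <- g0 + seq_len(module_sizes[m])
      values[idx, ] <- sqrt(rho) * matrix(f, length(idx), n, byrow = TRUE) +
        sqrt(1 - rho) * values[idx, , drop = FALSE]
      g0 <- g0 + module_sizes[m]
    }
    rownames(values) <- gene_names
    if (with_reg) {
      if (is.null(f1)) f1 <- stats::rnorm(n)
      reg <- sqrt(reg_rho) * f1 + sqrt(1 - reg_rho) * stats::rnorm(n)
      values <- rbind(values, regulator = reg)
    }
    colnames(values) <- sprintf("%s%03d", prefix, seq_len(n))
    expression_matrix(values, unit = "log2")
  }

  cases <- cohort(n_cases, corr_cases, regulator_loading_cases, "case")
  controls <- cohort(n_controls, corr_controls, regulator_loading_controls, "ctrl")
  assignments <- stats::setNames(labels, gene_names)
  if (with_reg) assignments <- c(assignments, regulator = "regulator")
  truth <- synthetic_truth(assignments,
                           module_corr_cases = corr_cases,
                           module_corr_controls = corr_controls, seed = seed)
  list(cases = cases, controls = controls, truth = truth)
}

#' Generate fibrosis-like traits loaded on the module eigengene
#'
#' Two traits (interstitial and perivascular fibrosis analogues) are
#' generated as `trait_loading * eigengene + confounder_loading * BP +
#' noise`, where the eigengene is the first principal component of the
#' planted module (standardized across samples) and BP is an independent
#' `N(0, 1)` blood-pressure-like covariate emitted alongside.
#'
#' @param expr An `ExpressionMatrix` containing the module genes.
#' @param truth A `SyntheticTruth` whose first planted module (`"P1"`)
#'   defines the eigengene.
#' @param trait_loading,confounder_loading Loadings (defaults 1 and 0.5).
#' @param noise_sd Trait noise SD (default 0.5).
#' @param seed Integer seed.
#' @return List with `pheno` (a `PhenotypeTable` with traits
#'   `interstitial_fibrosis`, `perivascular_fibrosis` and covariate
#'   `mean_bp`) and `truth` (updated with the loadings).
#' @export
generate_phenotype <- function(expr, truth, trait_loading = 1,
                               confounder_loading = 0.5, noise_sd = 0.5,
                               seed = 1) {
  mg <- names(truth$module_assignments)[truth$module_assignments == "P1"]
  missing <- setdiff(mg, gene_ids(expr))
  if (length(missing))
    stop("module genes absent from expression matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  if (length(mg) < 2) stop("planted module P1 must have >= 2 genes")
  eg <- module_eigengene(expr, mg)
  z <- as.numeric(scale(eg$loadings))
  n <- length(z)
  set.seed(seed)
  bp <- stats::rnorm(n)
  traits <- data.frame(
    interstitial_fibrosis = trait_loading * z + confounder_loading * bp +
      stats::rnorm(n, sd = noise_sd),
    perivascular_fibrosis = trait_loading * z + confounder_loading * bp +
      stats::rnorm(n, sd = noise_sd))
  truth$trait_loading <- trait_loading
  truth$confounder_loading <- confounder_loading
  list(pheno = phenotype_table(sample_ids(expr), traits,
                               data.frame(mean_bp = bp)),
       truth = truth)
}
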