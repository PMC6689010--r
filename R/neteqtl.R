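# Genetic mapping of a module's joint expression: LD-block pruning to
# representative SNPs, per-gene sparse Bayesian variable selection giving
# marginal posterior inclusion probabilities (MPPI), conversion to Bayes
# factors through the inclusion prior pi = E(p_g)/p, median-BF locus
# calling, syntenic-window translation between species, and isoform-level
# cis mapping with Kruskal-Wallis genotype-group tests.
#
# Model, per response y (one gene) against standardized dosages X:
# inclusion indicators gamma_j ~ Bernoulli(pi); included coefficients get
# a Zellner g-prior with g = n; the residual variance is integrated out
# under a vague prior, giving the closed-form marginal likelihood
#   m(gamma) ~ (1+g)^(-q/2) * [y'y - g/(1+g) SSR_gamma]^(-(n-1)/2)
# (y centered, q = |gamma|). The posterior over gamma is explored by
# Metropolis-Hastings with add/delete/swap moves; the same marginal
# likelihood summed over all 2^p models gives an exact small-p reference.

#' Prune genotypes to one representative SNP per LD block
#'
#' Within each block the SNP with the highest average Spearman correlation
#' to the other block members is kept (ties broken by input order;
#' singleton blocks keep their SNP). SNPs outside any block pass through
#' unchanged and are appended after the block representatives.
#'
#' @param genotypes A `GenotypeMatrix` with `block_id` set.
#' @return The pruned `GenotypeMatrix`.
#' @export
prune_ld_blocks <- function(genotypes) {
  blk <- genotypes$block_id
  blockless <- which(is.na(blk))
  reps <- integer(0)
  for (b in unique(blk[!is.na(blk)])) {
    idx <- which(blk == b)
    if (length(idx) == 1) { reps <- c(reps, idx); next }
    sc <- suppressWarnings(
      stats::cor(t(genotypes$dosage[idx, , drop = FALSE]),
                 method = "spearman"))
    diag(sc) <- NA
    mean_cor <- rowMeans(sc, na.rm = TRUE)
    mean_cor[is.nan(mean_cor)] <- -Inf
    reps <- c(reps, idx[which.max(mean_cor)])  # which.max: first on ties
  }
  keep <- c(reps, blockless)
  genotype_matrix(genotypes$dosage[keep, , drop = FALSE],
                  genotypes$chrom[keep], genotypes$pos[keep],
                  genotypes$block_id[keep], ploidy = genotypes$ploidy)
}

# Closed-form log marginal likelihood environment for one (y, X) pair.
# Returns a function(model index vector) -> log m(gamma), with caching.
.make_log_marginal <- function(y, X) {
  n <- length(y)
  yc <- y - mean(y)
  yty <- sum(yc^2)
  Xs <- scale(X)
  XtX <- crossprod(Xs)
  Xty <- drop(crossprod(Xs, yc))
  g <- n
  shrink <- g / (1 + g)
  cache <- new.env(hash = TRUE, parent = emptyenv())
  function(idx) {
    q <- length(idx)
    if (q == 0) return(-(n - 1) / 2 * log(yty))
    key <- paste(idx, collapse = ",")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    ssr <- tryCatch({
      R <- chol(XtX[idx, idx, drop = FALSE])
      z <- backsolve(R, Xty[idx], transpose = TRUE)
      sum(z^2)
    }, error = function(e) {
      # rank-deficient submodel (e.g. duplicated SNPs): project via QR
      h <- qr(Xs[, idx, drop = FALSE])
      sum(qr.fitted(h, yc)^2)
    })
    s2 <- max(yty - shrink * ssr, yty * 1e-12)
    val <- -q / 2 * log1p(g) - (n - 1) / 2 * log(s2)
    cache[[key]] <- val
    val
  }
}

#' Spike-and-slab variable selection by Metropolis-Hastings
#'
#' Bayesian variable selection of SNP predictors for one expression
#' response. Indicators are Bernoulli(`pi`) with `pi = e_pg / p`;
#' included coefficients carry a Zellner g-prior with `g = n`; the
#' closed-form marginal likelihood (coefficients and residual variance
#' integrated out) drives a Metropolis-Hastings chain over models with
#' add/delete/swap proposals. The MPPI of predictor `j` is its posterior
#' inclusion frequency after burn-in.
#'
#' @param y Numeric response (>= 10 samples, finite).
#' @param X Dosage matrix, samples x SNPs; columns are standardized
#'   internally, so dosage rescaling does not change the result.
#'   Zero-variance columns are excluded from sampling and reported at the
#'   prior with a flag.
#' @param e_pg Prior expected number of control points per gene
#'   (default 2).
#' @param n_iter Total MH iterations (default 10000).
#' @param n_burnin Burn-in iterations (default 20% of `n_iter`).
#' @param seed Integer seed.
#' @return Numeric MPPI vector (one per SNP column) with attributes
#'   `prior_pi`, `flagged` (zero-variance columns) and `accept_rate`.
#' @export
spike_slab_mppi <- function(y, X, e_pg = 2, n_iter = 10000,
                            n_burnin = floor(n_iter / 5), seed = 1) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (p == 0) stop("no predictors")
  if (any(!is.finite(y))) stop("non-finite response")
  n <- length(y)
  if (n < 10) stop("need at least 10 samples")
  if (nrow(X) != n) stop("X must have one row per sample")
  prior_pi <- e_pg / p
  if (prior_pi >= 1) stop("e_pg must be smaller than the SNP count")
  sds <- apply(X, 2, stats::sd)
  flagged <- sds == 0
  active <- which(!flagged)
  mppi <- rep(prior_pi, p)
  if (length(active) == 0) {
    warning("all predictor columns are constant")
    attr(mppi, "prior_pi") <- prior_pi
    attr(mppi, "flagged") <- flagged
    attr(mppi, "accept_rate") <- NA_real_
    return(mppi)
  }
  pa <- length(active)
  log_marg <- .make_log_marginal(y, X[, active, drop = FALSE])
  log_prior_odds <- log(prior_pi) - log1p(-prior_pi)

  set.seed(seed)
  model <- integer(0)                  # indices into `active`, kept sorted
  cur_lm <- log_marg(model)
  counts <- numeric(pa)
  accepted <- 0L
  kept <- n_iter - n_burnin
  for (it in seq_len(n_iter)) {
    q <- length(model)
    move <- sample.int(3L, 1L)
    if (move == 1L && q < pa) {            # add
      out_set <- setdiff(seq_len(pa), model)
      j <- out_set[sample.int(length(out_set), 1L)]
      prop <- sort(c(model, j))
      lm_new <- log_marg(prop)
      log_alpha <- lm_new - cur_lm + log_prior_odds +
        log(pa - q) - log(q + 1)
    } else if (move == 2L && q > 0) {      # delete
      j <- model[sample.int(q, 1L)]
      prop <- setdiff(model, j)
      lm_new <- log_marg(prop)
      log_alpha <- lm_new - cur_lm - log_prior_odds +
        log(q) - log(pa - q + 1)
    } else if (move == 3L && q > 0 && q < pa) {  # swap
      j_out <- model[sample.int(q, 1L)]
      out_set <- setdiff(seq_len(pa), model)
      j_in <- out_set[sample.int(length(out_set), 1L)]
      prop <- sort(c(setdiff(model, j_out), j_in))
      lm_new <- log_marg(prop)
      log_alpha <- lm_new - cur_lm
    } else {
      prop <- model; lm_new <- cur_lm; log_alpha <- -Inf  # unavailable move
    }
    if (log(stats::runif(1)) < log_alpha) {
      model <- prop
      cur_lm <- lm_new
      accepted <- accepted + 1L
    }
    if (it > n_burnin && length(model))
      counts[model] <- counts[model] + 1
  }
  mppi[active] <- counts / kept
  attr(mppi, "prior_pi") <- prior_pi
  attr(mppi, "flagged") <- flagged
  attr(mppi, "accept_rate") <- accepted / n_iter
  names(mppi) <- colnames(X)
  mppi
}

#' Exact posterior inclusion probabilities by model enumeration
#'
#' Sums the closed-form marginal likelihood times the Bernoulli(`pi`)
#' model prior over all `2^p` models; the small-`p` reference the
#' Metropolis-Hastings sampler is validated against.
#'
#' @inheritParams spike_slab_mppi
#' @param X Dosage matrix with at most 15 columns.
#' @return Numeric MPPI vector with attribute `prior_pi`.
#' @export
exact_mppi_enumeration <- function(y, X, e_pg = 2) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (p > 15) stop("enumeration limited to p <= 15")
  if (p == 0) stop("no predictors")
  prior_pi <- e_pg / p
  if (prior_pi >= 1) stop("e_pg must be smaller than the SNP count")
  log_marg <- .make_log_marginal(y, X)
  log_odds <- log(prior_pi) - log1p(-prior_pi)
  n_models <- 2^p
  logw <- numeric(n_models)
  members <- vector("list", n_models)
  for (m in seq_len(n_models) - 1L) {
    idx <- which(bitwAnd(m, bitwShiftL(1L, seq_len(p) - 1L)) != 0L)
    members[[m + 1L]] <- idx
    logw[m + 1L] <- log_marg(idx) + length(idx) * log_odds
  }
  logw <- logw - max(logw)
  w <- exp(logw) / sum(exp(logw))
  mppi <- numeric(p)
  for (m in seq_len(n_models)) {
    if (length(members[[m]])) mppi[members[[m]]] <- mppi[members[[m]]] + w[m]
  }
  names(mppi) <- colnames(X)
  attr(mppi, "prior_pi") <- prior_pi
  mppi
}

#' Convert MPPI to a Bayes factor
#'
#' `BF = [MPPI / (1 - MPPI)] / [pi / (1 - pi)]`: the ratio of posterior to
#' prior odds of inclusion. `BF = 1` means the data moved nothing.
#'
#' @param mppi Posterior inclusion probability in `[0, 1)` (values of 1
#'   must be capped upstream; see [network_eqtl_map()]).
#' @param prior_pi Prior inclusion probability in `(0, 1)`.
#' @return Nonnegative Bayes factor (vectorized).
#' @export
mppi_to_bf <- function(mppi, prior_pi) {
  if (any(mppi < 0 | mppi >= 1)) stop("mppi must lie in [0, 1)")
  if (prior_pi <= 0 || prior_pi >= 1) stop("prior_pi must lie in (0, 1)")
  (mppi / (1 - mppi)) / (prior_pi / (1 - prior_pi))
}

#' Map a module's joint expression to the genome
#'
#' Runs [spike_slab_mppi()] for every module gene against the full
#' (pruned) SNP matrix under the shared prior `pi = e_pg / p`, converts
#' MPPIs to Bayes factors (MPPI capped at `1 - 1/(2 n_iter)` first), and
#' summarizes each SNP by the median BF across module genes. A SNP is
#' called a network regulatory locus when its median BF exceeds
#' `bf_threshold`.
#'
#' @param expr An `ExpressionMatrix` holding the module genes.
#' @param genes Module gene ids.
#' @param genotypes A (pruned) `GenotypeMatrix` over the same samples.
#' @param e_pg Prior expected control points per gene (default 2).
#' @param n_iter,n_burnin,seed Sampler controls (per-gene seeds are
#'   derived from `seed`).
#' @param bf_threshold Median-BF call threshold (default 100).
#' @return List of class `NetworkEqtl`: `mppi` and `bf` (genes x SNPs
#'   matrices), `prior_pi`, `summary` (per-SNP data frame with
#'   `median_bf`, `n_genes_bf_gt_threshold`, `called`), `failed_genes`,
#'   and `sampler` (diagnostics).
#' @export
network_eqtl_map <- function(expr, genes, genotypes, e_pg = 2,
                             n_iter = 10000, n_burnin = floor(n_iter / 5),
                             seed = 1, bf_threshold = 100) {
  missing <- setdiff(genes, gene_ids(expr))
  if (length(missing))
    stop("module genes absent from expression: ",
         paste(utils::head(missing, 5), collapse = ", "))
  samples <- intersect(sample_ids(expr), colnames(genotypes$dosage))
  if (length(samples) < 10) stop("fewer than 10 samples shared with genotypes")
  X <- t(genotypes$dosage[, samples, drop = FALSE])
  p <- ncol(X)
  prior_pi <- e_pg / p
  mppi <- matrix(NA_real_, length(genes), p,
                 dimnames = list(genes, rownames(genotypes$dosage)))
  failed <- character(0)
  for (i in seq_along(genes)) {
    y <- expr$values[genes[i], samples]
    res <- tryCatch(
      spike_slab_mppi(y, X, e_pg = e_pg, n_iter = n_iter,
                      n_burnin = n_burnin, seed = seed + i),
      error = function(e) NULL)
    if (is.null(res)) failed <- c(failed, genes[i]) else mppi[i, ] <- res
  }
  if (length(failed)) {
    warning("sampler failed for ", length(failed),
            " gene(s); summary computed over the rest")
    mppi <- mppi[!rownames(mppi) %in% failed, , drop = FALSE]
  }
  cap <- 1 - 1 / (2 * n_iter)
  capped <- mppi > cap
  mppi_c <- pmin(mppi, cap)
  bf <- matrix(mppi_to_bf(as.numeric(mppi_c), prior_pi), nrow(mppi), p,
               dimnames = dimnames(mppi))
  med <- apply(bf, 2, stats::median)
  n_hi <- colSums(bf > bf_threshold)
  summary <- data.frame(snp_id = colnames(bf), chrom = genotypes$chrom,
                        pos = genotypes$pos, median_bf = med,
                        n_genes_bf_gt_threshold = as.integer(n_hi),
                        called = med > bf_threshold, row.names = NULL)
  structure(list(mppi = mppi, bf = bf, prior_pi = prior_pi,
                 summary = summary, failed_genes = failed,
                 capped = which(capped, arr.ind = TRUE),
                 sampler = list(n_iter = n_iter, n_burnin = n_burnin,
                                seed = seed, e_pg = e_pg)),
            class = "NetworkEqtl")
}

#' @export
print.NetworkEqtl <- function(x, ...) {
  called <- x$summary$snp_id[x$summary$called]
  cat(sprintf("NetworkEqtl: %d genes x %d SNPs, prior pi = %.3g\n",
              nrow(x$bf), ncol(x$bf), x$prior_pi))
  cat(sprintf("  max median BF = %.1f; called loci: %s\n",
              max(x$summary$median_bf),
              if (length(called)) paste(called, collapse = ", ") else "none"))
  invisible(x)
}

#' Translate a mapped locus to the syntenic window in another species
#'
#' Computes the center of the source haplotype block
#' (`start + (end - start) / 2`), finds the nearest source-species gene
#' (by distance from its midpoint; walking outward to the nearest gene
#' with an ortholog; equidistant candidates resolve to the smaller start
#' coordinate), maps it through the one-to-one ortholog table, and
#' returns a window of `window_mb` Mb centered on the ortholog gene's
#' midpoint (1-based, clipped at 1).
#'
#' @param block A `GenomicInterval` for the source haplotype block.
#' @param genes_src Data frame of source-species genes: `gene_id`,
#'   `chrom`, `start`, `end`.
#' @param map An `OrthologMap` (`gene_a` = source ids, `gene_b` = target
#'   ids).
#' @param genes_tgt Data frame of target-species genes, same columns.
#' @param window_mb Window size in Mb (default 10).
#' @return A `GenomicInterval` in target coordinates with attributes
#'   `anchor_gene_src` and `anchor_gene_tgt`.
#' @export
syntenic_window <- function(block, genes_src, map, genes_tgt,
                            window_mb = 10) {
  stopifnot(inherits(block, "GenomicInterval"))
  center <- block$start + (block$end - block$start) / 2
  cand <- genes_src[genes_src$chrom == block$chrom &
                      genes_src$gene_id %in% map$gene_a, , drop = FALSE]
  if (!nrow(cand))
    stop("no mappable gene with an ortholog on chromosome ", block$chrom)
  mid <- cand$start + (cand$end - cand$start) / 2
  dist <- abs(mid - center)
  best <- which(dist == min(dist))
  if (length(best) > 1) best <- best[which.min(cand$start[best])]
  src_gene <- cand$gene_id[best]
  tgt_gene <- map$gene_b[match(src_gene, map$gene_a)]
  row <- genes_tgt[genes_tgt$gene_id == tgt_gene, , drop = FALSE]
  if (!nrow(row)) stop("ortholog ", tgt_gene, " missing from target table")
  tgt_center <- row$start[1] + (row$end[1] - row$start[1]) / 2
  half <- window_mb * 1e6 / 2
  iv <- genomic_interval(row$chrom[1], max(1, tgt_center - half),
                         tgt_center + half)
  attr(iv, "anchor_gene_src") <- src_gene
  attr(iv, "anchor_gene_tgt") <- tgt_gene
  iv
}

#' Cis mapping of isoform expression within a window
#'
#' Restricts SNPs to the window (prior `pi` recomputed with the windowed
#' SNP count), runs [spike_slab_mppi()] per isoform, and reports for each
#' isoform a Kruskal-Wallis test of expression across genotype groups at
#' its lead SNP (highest MPPI), with Benjamini-Hochberg FDR across
#' isoforms. Genotype groups with fewer than 2 samples are dropped with a
#' warning; if fewer than 2 groups remain, P is set to 1 and flagged.
#'
#' @param isoform_expr An `ExpressionMatrix` of isoform-level expression.
#' @param genotypes A `GenotypeMatrix`.
#' @param window A `GenomicInterval` restricting the SNPs.
#' @param e_pg,n_iter,n_burnin,seed Sampler controls.
#' @param lead_snp The regulatory SNP at which genotype groups are formed
#'   for every isoform. `NULL` (default) picks the windowed SNP with the
#'   highest MPPI over all isoforms; a single shared SNP avoids
#'   per-isoform selection bias in the Kruskal-Wallis P values.
#' @return List with `mppi`, `bf`, `prior_pi`, `lead_snp` and `kw` (data
#'   frame: `isoform`, `lead_snp`, `lead_mppi`, `lead_bf`, `kw_h`,
#'   `kw_p`, `fdr`, `flagged`).
#' @export
cis_isoform_eqtl <- function(isoform_expr, genotypes, window, e_pg = 2,
                             n_iter = 10000, n_burnin = floor(n_iter / 5),
                             seed = 1, lead_snp = NULL) {
  in_win <- genotypes$chrom == window$chrom &
    genotypes$pos >= window$start & genotypes$pos <= window$end
  if (!any(in_win)) stop("no SNPs inside the window")
  sub <- genotype_matrix(genotypes$dosage[in_win, , drop = FALSE],
                         genotypes$chrom[in_win], genotypes$pos[in_win],
                         genotypes$block_id[in_win], ploidy = genotypes$ploidy)
  res <- network_eqtl_map(isoform_expr, gene_ids(isoform_expr), sub,
                          e_pg = e_pg, n_iter = n_iter, n_burnin = n_burnin,
                          seed = seed, bf_threshold = 100)
  if (is.null(lead_snp)) {
    best <- apply(res$mppi, 2, max)      # strongest signal over isoforms
    lead_snp <- colnames(res$mppi)[which.max(best)]
  } else if (!lead_snp %in% rownames(sub$dosage)) {
    stop("lead SNP ", lead_snp, " is not inside the window")
  }
  samples <- intersect(sample_ids(isoform_expr), colnames(sub$dosage))
  rows <- lapply(rownames(res$mppi), function(iso) {
    kw <- kruskal_by_genotype(isoform_expr$values[iso, samples],
                              sub$dosage[lead_snp, samples])
    data.frame(isoform = iso, lead_snp = lead_snp,
               lead_mppi = res$mppi[iso, lead_snp],
               lead_bf = res$bf[iso, lead_snp], kw_h = kw$statistic,
               kw_p = kw$p.value, flagged = kw$flagged)
  })
  kw_tab <- do.call(rbind, rows)
  kw_tab$fdr <- stats::p.adjust(kw_tab$kw_p, method = "fdr")
  rownames(kw_tab) <- NULL
  list(mppi = res$mppi, bf = res$bf, prior_pi = res$prior_pi,
       lead_snp = lead_snp, kw = kw_tab)
}

#' Kruskal-Wallis test of expression across genotype groups
#'
#' Tie-corrected H with the chi-square approximation
#' (df = groups - 1), via `stats::kruskal.test`. Groups with fewer than
#' 2 samples are dropped with a warning; with fewer than 2 groups left
#' the result is `H = 0, P = 1`, flagged.
#'
#' @param y Numeric expression vector.
#' @param genotype Genotype codes (grouping).
#' @return List with `statistic`, `p.value`, `flagged`.
#' @export
kruskal_by_genotype <- function(y, genotype) {
  genotype <- as.factor(genotype)
  sizes <- table(genotype)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("dropping genotype group(s) with < 2 samples: ",
            paste(small, collapse = ", "))
    keep <- !genotype %in% small
    y <- y[keep]; genotype <- droplevels(genotype[keep])
  }
  if (nlevels(genotype) < 2 || length(unique(y)) < 2)
    return(list(statistic = 0, p.value = 1, flagged = TRUE))
  kt <- stats::kruskal.test(y, genotype)
  list(statistic = unname(kt$statistic), p.value = kt$p.value,
       flagged = FALSE)
}
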