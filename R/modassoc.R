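# Module-trait association: gene-level Spearman ranking and a classic
# (unweighted) pre-ranked GSEA engine with gene-label permutation nulls.
# Genes are ranked by correlation P value with the LARGEST P first, so
# trait-associated modules surface as a significant NEGATIVE normalized
# enrichment score.

#' Rank genes by trait correlation
#'
#' Per gene, the Spearman correlation with the trait and its Student-t
#' P value (`t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` df). The
#' output is sorted descending by P value (largest P first), so
#' trait-associated genes sit at the bottom of the list.
#'
#' @param expr An `ExpressionMatrix` with >= 5 samples.
#' @param trait Numeric vector, one value per sample.
#' @return A data frame of class `RankedGeneList` with columns `gene_id`,
#'   `rho`, `metric` (the P value), sorted descending by `metric`.
#' @export
rank_genes_by_trait <- function(expr, trait) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  n <- ncol(expr$values)
  if (length(trait) != n) stop("trait length must equal the sample count")
  if (n < 5) stop("need at least 5 samples")
  if (stats::sd(trait) == 0) {
    warning("constant trait: all P values set to 1")
    rho <- rep(0, nrow(expr$values))
  } else {
    tr <- rank(trait, ties.method = "average")
    rho <- apply(expr$values, 1, function(g) {
      if (stats::sd(g) == 0) return(NA_real_)
      stats::cor(rank(g, ties.method = "average"), tr)
    })
  }
  p <- rep(1, length(rho))
  ok <- !is.na(rho)
  if (any(!ok)) warning(sum(!ok), " constant gene(s): P set to 1")
  tval <- rho[ok] * sqrt((n - 2) / pmax(1 - rho[ok]^2, .Machine$double.eps))
  p[ok] <- 2 * stats::pt(-abs(tval), df = n - 2)
  rho[!ok] <- 0
  out <- data.frame(gene_id = gene_ids(expr), rho = rho, metric = p)
  out <- out[order(-out$metric), ]
  rownames(out) <- NULL
  class(out) <- c("RankedGeneList", "data.frame")
  out
}

# Classic (unweighted) enrichment score from sorted hit positions:
# walking down the list, hits add 1/Nh and misses subtract 1/(N - Nh);
# the ES is the signed maximum deviation from zero. Only the running sum
# at hit entry/exit points needs evaluating.
.es_from_positions <- function(pos, N) {
  nh <- length(pos)
  pos <- sort(pos)
  j <- seq_len(nh)
  at_hit <- j / nh - (pos - j) / (N - nh)       # just after each hit
  before_hit <- (j - 1) / nh - (pos - j) / (N - nh) # just before each hit
  mx <- max(at_hit)                             # running-sum maxima sit at hits
  mn <- min(before_hit)                         # minima sit just before hits
  # exact +-ties resolve to the positive deviation; the tolerance guards
  # against last-ulp rounding of the rational increments
  if (mx >= -mn - 1e-9) mx else mn
}

#' Classic pre-ranked GSEA
#'
#' Runs the unweighted running-sum enrichment statistic of each gene set
#' against a ranked gene list, with a gene-label permutation null:
#' `n_perm` random same-size sets per set size. `NES = ES / mean(|null ES|
#' of matching sign)`; the nominal P is the fraction of same-sign null ES
#' at least as extreme; the FDR q follows the positive/negative-tail
#' normalized-ES procedure of the reference GSEA method. Sets are
#' intersected with the ranked universe before size filtering.
#'
#' @param ranked A `RankedGeneList` from [rank_genes_by_trait()] (or any
#'   data frame with `gene_id` ordered by the ranking metric).
#' @param gene_sets Named list of character vectors.
#' @param n_perm Number of permutations (default 10000).
#' @param min_size,max_size Gene set size bounds after intersection
#'   (defaults 10 and 5000).
#' @param seed Integer seed for the permutation null.
#' @return Data frame with columns `set`, `size`, `es`, `nes`,
#'   `nominal_p`, `fdr_q`.
#' @export
gsea_preranked <- function(ranked, gene_sets, n_perm = 10000, min_size = 10,
                           max_size = 5000, seed = 1) {
  universe <- ranked$gene_id
  N <- length(universe)
  sets <- lapply(gene_sets, intersect, y = universe)
  empty <- names(sets)[vapply(sets, length, 0L) == 0 &
                         vapply(gene_sets, length, 0L) > 0]
  if (length(empty))
    message("skipping sets with empty universe intersection: ",
            paste(empty, collapse = ", "))
  sizes <- vapply(sets, length, 0L)
  keep <- sizes >= min_size & sizes <= max_size
  sets <- sets[keep]
  if (!length(sets))
    return(data.frame(set = character(), size = integer(), es = numeric(),
                      nes = numeric(), nominal_p = numeric(),
                      fdr_q = numeric()))
  sizes <- sizes[keep]

  es_obs <- vapply(seq_along(sets), function(i)
    .es_from_positions(match(sets[[i]], universe), N), 0)

  set.seed(seed)
  null_by_size <- list()
  for (k in sort(unique(sizes))) {
    null_by_size[[as.character(k)]] <- vapply(seq_len(n_perm), function(b)
      .es_from_positions(sample.int(N, k), N), 0)
  }

  nes <- nominal_p <- numeric(length(sets))
  null_nes_all <- list()
  for (i in seq_along(sets)) {
    null_es <- null_by_size[[as.character(sizes[i])]]
    pos_mean <- mean(null_es[null_es >= 0])
    neg_mean <- mean(abs(null_es[null_es < 0]))
    if (es_obs[i] >= 0) {
      same <- null_es[null_es >= 0]
      nes[i] <- if (is.nan(pos_mean)) NA_real_ else es_obs[i] / pos_mean
      nominal_p[i] <- if (length(same)) mean(same >= es_obs[i]) else NA_real_
    } else {
      same <- null_es[null_es < 0]
      nes[i] <- if (is.nan(neg_mean)) NA_real_ else es_obs[i] / neg_mean
      nominal_p[i] <- if (length(same)) mean(same <= es_obs[i]) else NA_real_
    }
    # normalized null ES for the FDR pool
    nn <- ifelse(null_es >= 0,
                 null_es / pos_mean,
                 null_es / neg_mean)
    null_nes_all[[i]] <- nn[is.finite(nn)]
  }
  pool <- unlist(null_nes_all)

  fdr_q <- rep(NA_real_, length(sets))
  obs_pos <- nes[!is.na(nes) & nes >= 0]
  obs_neg <- nes[!is.na(nes) & nes < 0]
  pool_pos <- pool[pool >= 0]
  pool_neg <- pool[pool < 0]
  for (i in seq_along(sets)) {
    if (is.na(nes[i])) next
    if (nes[i] >= 0) {
      num <- if (length(pool_pos)) mean(pool_pos >= nes[i]) else 0
      den <- mean(obs_pos >= nes[i])
    } else {
      num <- if (length(pool_neg)) mean(pool_neg <= nes[i]) else 0
      den <- mean(obs_neg <= nes[i])
    }
    fdr_q[i] <- min(1, num / max(den, .Machine$double.eps))
  }
  # enforce monotonicity: larger |NES| never gets a larger q than smaller
  for (sgn in c(1, -1)) {
    idx <- which(!is.na(nes) & !is.na(fdr_q) &
                   (if (sgn == 1) nes >= 0 else nes < 0))
    if (length(idx) > 1) {
      ord <- idx[order(abs(nes[idx]))]          # ascending |NES|
      fdr_q[ord] <- cummin(fdr_q[ord])
    }
  }

  data.frame(set = names(sets), size = as.integer(sizes), es = es_obs,
             nes = nes, nominal_p = nominal_p, fdr_q = fdr_q,
             row.names = NULL)
}

#' Associate co-expression modules with traits
#'
#' Treats each module as a gene set, ranks all genes by the Student P of
#' their Spearman correlation with each trait (largest P first), and runs
#' classic pre-ranked GSEA. A module is called trait-associated when its
#' FDR q is below `fdr_cut` with a negative NES.
#'
#' @param modules A `ModuleSet`.
#' @param expr An `ExpressionMatrix` (samples must be covered by `pheno`).
#' @param pheno A `PhenotypeTable` whose traits are already adjusted
#'   (see [adjust_trait_for_covariate()]).
#' @param traits Trait column names to test.
#' @param n_perm,min_size,max_size,seed Passed to [gsea_preranked()].
#' @param fdr_cut Association threshold (default 0.05).
#' @return Named list (per trait) of GSEA result tables with an extra
#'   logical column `associated`.
#' @export
associate_modules <- function(modules, expr, pheno, traits, n_perm = 10000,
                              min_size = 10, max_size = 5000, seed = 1,
                              fdr_cut = 0.05) {
  stopifnot(inherits(modules, "ModuleSet"), inherits(pheno, "PhenotypeTable"))
  missing <- setdiff(traits, names(pheno$traits))
  if (length(missing))
    stop("traits not found: ", paste(missing, collapse = ", "))
  idx <- match(sample_ids(expr), pheno$sample_ids)
  if (anyNA(idx)) stop("expression samples missing from the phenotype table")
  sets <- modules_as_gene_sets(modules)
  out <- list()
  for (tr in traits) {
    ranked <- rank_genes_by_trait(expr, pheno$traits[[tr]][idx])
    res <- gsea_preranked(ranked, sets, n_perm = n_perm, min_size = min_size,
                          max_size = max_size, seed = seed)
    res$associated <- !is.na(res$fdr_q) & res$fdr_q < fdr_cut &
      !is.na(res$nes) & res$nes < 0
    out[[tr]] <- res
  }
  out
}
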