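# Co-expression module inference: soft-threshold adjacency on the robust
# correlation matrix, topological overlap, average-linkage clustering with
# a static height cut, eigengene computation and eigengene-based merging.
# The network is unsigned (adjacency = |bicor|^beta).

#' Scale-free fit diagnostics and soft-threshold selection
#'
#' For each candidate exponent `beta`, the unsigned adjacency
#' `a = |corr|^beta` gives connectivities `k_i = sum_{j != i} a_ij`. The
#' scale-free fit R^2 is the coefficient of determination of
#' `log10 p(k) ~ log10 k` over 10 equal-count connectivity bins (bin-mean
#' connectivity; empty bins dropped; fewer than 3 usable bins makes R^2
#' undefined for that `beta`). Among candidates with `R^2 > r2_cut` the
#' one with the highest mean connectivity is chosen (ties: smallest
#' `beta`); when none qualifies, the `beta` with the highest R^2 is
#' returned with `flagged = TRUE`.
#'
#' @param corr Symmetric correlation matrix (e.g. from [bicor_matrix()]).
#' @param candidate_betas Integer candidates, all >= 1 (default 1:20).
#' @param r2_cut Scale-free fit threshold (default 0.8).
#' @return List with `beta`, `flagged`, and `diagnostics` (data frame with
#'   columns `beta`, `scale_free_r2`, `mean_connectivity`).
#' @export
pick_soft_threshold <- function(corr, candidate_betas = 1:20, r2_cut = 0.8) {
  if (!length(candidate_betas) || any(candidate_betas < 1))
    stop("candidate_betas must be non-empty and all >= 1")
  diag_tab <- data.frame(beta = candidate_betas,
                         scale_free_r2 = NA_real_,
                         mean_connectivity = NA_real_)
  a0 <- abs(corr)
  diag(a0) <- 0
  for (i in seq_along(candidate_betas)) {
    a <- a0^candidate_betas[i]
    k <- rowSums(a)
    diag_tab$mean_connectivity[i] <- mean(k)
    diag_tab$scale_free_r2[i] <- scale_free_r2(k)
  }
  select_beta(diag_tab, r2_cut)
}

#' Scale-free topology fit of a connectivity vector
#'
#' Discretizes the connectivities into `n_bins` equal-width bins, drops
#' zero-count bins, and regresses the log10 frequency per bin on the
#' log10 of the bin-mean connectivity.
#'
#' @param k Nonnegative connectivity vector.
#' @param n_bins Number of equal-width bins (default 10).
#' @return R^2 of the log10-log10 fit, or `NA` when fewer than 3 usable
#'   bins remain.
#' @export
scale_free_r2 <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(k) < n_bins) return(NA_real_)
  breaks <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- findInterval(k, breaks, rightmost.closed = TRUE)
  counts <- tabulate(bin, n_bins)
  keep <- counts > 0
  if (sum(keep) < 3) return(NA_real_)
  k_mean <- vapply(which(keep), function(b) mean(k[bin == b]), 0)
  p_k <- counts[keep] / length(k)
  fit <- stats::lm(log10(p_k) ~ log10(k_mean))
  summary(fit)$r.squared
}

#' Apply the soft-threshold selection rule to a diagnostics table
#'
#' @param diagnostics Data frame with columns `beta`, `scale_free_r2`,
#'   `mean_connectivity`.
#' @param r2_cut Scale-free fit threshold.
#' @return List with `beta`, `flagged` and `diagnostics`.
#' @export
select_beta <- function(diagnostics, r2_cut = 0.8) {
  ok <- !is.na(diagnostics$scale_free_r2) & diagnostics$scale_free_r2 > r2_cut
  if (any(ok)) {
    cand <- diagnostics[ok, ]
    best <- cand$beta[cand$mean_connectivity == max(cand$mean_connectivity)]
    list(beta = min(best), flagged = FALSE, diagnostics = diagnostics)
  } else {
    if (all(is.na(diagnostics$scale_free_r2)))
      stop("scale-free R^2 undefined for every candidate beta")
    best <- diagnostics$beta[which.max(diagnostics$scale_free_r2)]
    list(beta = best, flagged = TRUE, diagnostics = diagnostics)
  }
}

#' Topological overlap similarity
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' unit diagonal; the sum runs over shared neighbors `u != i, j`.
#'
#' @param adjacency Symmetric nonnegative matrix with entries in `[0, 1]`
#'   (the diagonal is ignored).
#' @return Symmetric TOM matrix with entries in `[0, 1]` and unit diagonal.
#' @export
tom_similarity <- function(adjacency) {
  if (any(adjacency < 0)) stop("adjacency entries must be nonnegative")
  if (any(adjacency > 1)) stop("adjacency entries must be <= 1")
  a <- adjacency
  diag(a) <- 0
  k <- rowSums(a)
  shared <- a %*% a
  kmin <- outer(k, k, pmin)
  tom <- (shared + a) / (kmin + 1 - a)
  diag(tom) <- 1
  tom <- (tom + t(tom)) / 2
  dimnames(tom) <- dimnames(adjacency)
  tom
}

#' Module eigengene
#'
#' First principal component of the module's gene-standardized expression
#' submatrix: the first right-singular vector across samples, unit norm,
#' sign-oriented so that its mean correlation with the member genes is
#' nonnegative.
#'
#' @param expr An `ExpressionMatrix`.
#' @param genes Character vector of member gene ids (>= 2 usable genes).
#' @return List with `loadings` (named numeric vector over samples),
#'   `var_explained`, and `genes`.
#' @export
module_eigengene <- function(expr, genes) {
  genes <- intersect(genes, gene_ids(expr))
  if (length(genes) < 2) stop("need at least 2 module genes present")
  sub <- expr$values[genes, , drop = FALSE]
  sds <- apply(sub, 1, stats::sd)
  usable <- sds > 0
  if (sum(usable) < 2) stop("need at least 2 non-constant module genes")
  z <- t(scale(t(sub[usable, , drop = FALSE])))
  sv <- svd(z, nu = 0, nv = 1)
  v <- sv$v[, 1]
  cors <- as.numeric(z %*% v)       # proportional to gene-eigengene correlation
  if (mean(cors) < 0) v <- -v
  names(v) <- colnames(sub)
  list(loadings = v, var_explained = sv$d[1]^2 / sum(sv$d^2), genes = genes)
}

#' Detect co-expression modules from a TOM
#'
#' Average-linkage hierarchical clustering on the dissimilarity `1 - TOM`,
#' cut statically at the absolute dissimilarity `cut_height`: genes that
#' only cohere above the cut (the weakly overlapping background) fall into
#' small fragments, which go to `"unassigned"` along with every cluster
#' below `min_size`. Eigengenes are computed per module and module pairs
#' whose eigengene dissimilarity (`1 - cor(eigengenes)`) is below
#' `merge_height` are merged iteratively (closest pair first) until none
#' remain. Retained modules are relabeled `M1..Mk` by decreasing size.
#'
#' @param tom TOM matrix from [tom_similarity()].
#' @param expr The `ExpressionMatrix` the TOM was derived from (used for
#'   eigengenes).
#' @param min_size Minimum module size (default 30).
#' @param cut_height Static cut on the `1 - TOM` scale (default 0.99, just
#'   below the dissimilarity of unconnected gene pairs).
#' @param merge_height Eigengene dissimilarity threshold below which
#'   modules merge (default 0.25; 0 disables merging).
#' @param beta Soft threshold recorded in the result's parameters.
#' @return List with `modules` (a `ModuleSet`) and `eigengenes` (named
#'   list of eigengene objects, one per retained module).
#' @export
detect_modules <- function(tom, expr, min_size = 30, cut_height = 0.99,
                           merge_height = 0.25, beta = NA_integer_) {
  if (min_size < 2) stop("min_size must be >= 2")
  genes <- rownames(tom)
  if (is.null(genes)) genes <- gene_ids(expr)
  tree <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  cl <- stats::cutree(tree, h = cut_height)
  names(cl) <- genes

  # provisional modules: clusters that meet min_size
  sizes <- table(cl)
  labels <- names(sizes)[sizes >= min_size]
  member_sets <- lapply(labels, function(l) genes[cl == as.integer(l)])
  if (!length(member_sets)) {
    warning("no cluster reaches min_size; all genes unassigned")
    ms <- module_set(stats::setNames(rep("unassigned", length(genes)), genes),
                     params = list(beta = beta, merge_height = merge_height,
                                   min_size = min_size))
    return(list(modules = ms, eigengenes = list()))
  }

  # iterative eigengene merging
  repeat {
    if (length(member_sets) < 2 || merge_height <= 0) break
    egs <- lapply(member_sets, function(g) module_eigengene(expr, g)$loadings)
    em <- do.call(cbind, egs)
    diss <- 1 - stats::cor(em)
    diag(diss) <- Inf
    min_d <- min(diss)
    if (min_d >= merge_height) break
    idx <- which(diss == min_d, arr.ind = TRUE)[1, ]
    merged <- c(member_sets[[idx[1]]], member_sets[[idx[2]]])
    member_sets <- member_sets[-c(idx[1], idx[2])]
    member_sets <- c(member_sets, list(merged))
  }

  # relabel M1..Mk by decreasing size (ties by first member's gene order)
  ord <- order(-vapply(member_sets, length, 0L),
               vapply(member_sets, function(g) match(g[1], genes), 0L))
  member_sets <- member_sets[ord]
  assignments <- stats::setNames(rep("unassigned", length(genes)), genes)
  for (m in seq_along(member_sets))
    assignments[member_sets[[m]]] <- paste0("M", m)
  ms <- module_set(assignments,
                   params = list(beta = beta, merge_height = merge_height,
                                 min_size = min_size))
  egs <- lapply(ms$module_order, function(l)
    module_eigengene(expr, module_genes(ms, l)))
  names(egs) <- ms$module_order
  list(modules = ms, eigengenes = egs)
}

#' Full module-inference chain
#'
#' Convenience wrapper: robust correlation, soft-threshold selection (or a
#' fixed `beta`), unsigned adjacency, TOM, and module detection.
#'
#' @inheritParams detect_modules
#' @param expr An `ExpressionMatrix`.
#' @param beta Soft threshold; `NULL` selects it via
#'   [pick_soft_threshold()].
#' @param candidate_betas Candidates for automatic selection.
#' @return As [detect_modules()], plus `beta` and `threshold_diagnostics`.
#' @export
infer_modules <- function(expr, beta = NULL, candidate_betas = 1:20,
                          min_size = 30, cut_height = 0.99,
                          merge_height = 0.25) {
  corr <- bicor_matrix(expr)
  diagnostics <- NULL
  if (is.null(beta)) {
    pick <- pick_soft_threshold(corr, candidate_betas)
    beta <- pick$beta
    diagnostics <- pick$diagnostics
  }
  adj <- abs(corr)^beta
  tom <- tom_similarity(adj)
  det <- detect_modules(tom, expr, min_size = min_size,
                        cut_height = cut_height,
                        merge_height = merge_height, beta = beta)
  c(det, list(beta = beta, threshold_diagnostics = diagnostics))
}
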