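# Cross-species module conservation (one-sided Fisher tests over a
# one-to-one ortholog background, Benjamini-Yekutieli corrected) and the
# empirical differential co-expression test (dispersion statistic with a
# random-gene-set permutation null).

#' One-to-one ortholog map
#'
#' @param gene_a,gene_b Character vectors of equal length; no gene may
#'   appear twice on either side.
#' @return An object of class `OrthologMap` (data frame with columns
#'   `gene_a`, `gene_b`).
#' @export
ortholog_map <- function(gene_a, gene_b) {
  if (length(gene_a) != length(gene_b)) stop("sides must have equal length")
  if (anyDuplicated(gene_a) || anyDuplicated(gene_b))
    stop("ortholog map must be one-to-one")
  structure(data.frame(gene_a = as.character(gene_a),
                       gene_b = as.character(gene_b),
                       stringsAsFactors = FALSE),
            class = c("OrthologMap", "data.frame"))
}

#' Restrict an ortholog map to genes expressed in both species
#'
#' @param map An `OrthologMap`.
#' @param genes_a,genes_b Robustly expressed gene sets on each side.
#' @return The background `OrthologMap` (pairs expressed on both sides).
#' @export
build_background <- function(map, genes_a, genes_b) {
  keep <- map$gene_a %in% genes_a & map$gene_b %in% genes_b
  if (!any(keep)) stop("empty ortholog background")
  ortholog_map(map$gene_a[keep], map$gene_b[keep])
}

#' Module conservation by Fisher's exact test
#'
#' Every (species-A module, species-B module) pair is tested for
#' overrepresented overlap by a one-sided (enrichment) Fisher exact test
#' on the 2x2 table over the ortholog background; module memberships are
#' first restricted to the background and species-B genes are translated
#' to their species-A orthologs. P values are adjusted across all
#' |A| x |B| tests by Benjamini-Yekutieli.
#'
#' @param modules_a,modules_b `ModuleSet` objects for the two species.
#' @param background A background `OrthologMap` from [build_background()].
#' @return Data frame with columns `module_a`, `module_b`, `size_a`,
#'   `size_b`, `overlap`, `fet_p`, `adjusted_p` (one row per tested pair;
#'   pairs where either module is empty after restriction are dropped
#'   with a message).
#' @export
conservation_test <- function(modules_a, modules_b, background) {
  sets_a <- lapply(modules_as_gene_sets(modules_a), intersect,
                   y = background$gene_a)
  # translate B modules into A-side ortholog ids
  b_to_a <- stats::setNames(background$gene_a, background$gene_b)
  sets_b <- lapply(modules_as_gene_sets(modules_b), function(g)
    unname(b_to_a[intersect(g, background$gene_b)]))
  n_bg <- nrow(background)
  rows <- list()
  skipped <- 0L
  for (la in names(sets_a)) for (lb in names(sets_b)) {
    ga <- sets_a[[la]]; gb <- sets_b[[lb]]
    if (!length(ga) || !length(gb)) { skipped <- skipped + 1L; next }
    ov <- length(intersect(ga, gb))
    tab <- matrix(c(ov, length(ga) - ov,
                    length(gb) - ov, n_bg - length(ga) - length(gb) + ov),
                  2, 2)
    p <- stats::fisher.test(tab, alternative = "greater")$p.value
    rows[[length(rows) + 1L]] <- data.frame(
      module_a = la, module_b = lb, size_a = length(ga), size_b = length(gb),
      overlap = ov, fet_p = p)
  }
  if (skipped) message(skipped, " module pair(s) empty after background restriction")
  out <- do.call(rbind, rows)
  out$adjusted_p <- stats::p.adjust(out$fet_p, method = "BY")
  rownames(out) <- NULL
  out
}

#' Dispersion statistic between two correlation matrices
#'
#' Root-mean-square difference of the pairwise correlations of a gene set
#' between two cohorts:
#' `D = sqrt(mean over pairs i < j of (r_cases_ij - r_controls_ij)^2)`.
#'
#' @param corr_cases,corr_controls Symmetric correlation matrices with
#'   gene-id dimnames.
#' @param genes Gene set (>= 2 genes, present in both matrices).
#' @return Nonnegative dispersion value.
#' @export
dispersion_statistic <- function(corr_cases, corr_controls, genes) {
  if (length(genes) < 2) stop("need at least 2 genes")
  miss_a <- setdiff(genes, rownames(corr_cases))
  miss_b <- setdiff(genes, rownames(corr_controls))
  if (length(miss_a) || length(miss_b))
    stop("genes missing from correlation matrices: ",
         paste(unique(c(miss_a, miss_b)), collapse = ", "))
  d <- corr_cases[genes, genes] - corr_controls[genes, genes]
  up <- d[upper.tri(d)]
  sqrt(mean(up^2))
}

#' Empirical P value for a permutation test
#'
#' `P = (r + 1) / (n + 1)` where `r` exceedances were seen in `n`
#' permutations; never zero by construction, so the minimum attainable
#' significance at `n` permutations is `1 / (n + 1)`.
#'
#' @param r_exceed Number of null statistics exceeding the observed one.
#' @param n_perm Number of permutations.
#' @return P value in `(0, 1]`.
#' @export
empirical_pvalue <- function(r_exceed, n_perm) {
  (r_exceed + 1) / (n_perm + 1)
}

#' Differential co-expression permutation test
#'
#' Computes the dispersion statistic of a module between the case and
#' control cohorts (biweight midcorrelation), then builds a null from
#' `n_perm` random gene sets of the same size drawn without replacement
#' from the shared gene universe, correlated on the same two cohorts.
#' The empirical P is `(r + 1) / (n + 1)` with `r` the number of null
#' dispersions strictly greater than the observed one; the Bonferroni
#' factor is the number of modules in the batch (`n_modules_tested`).
#'
#' @param expr_cases,expr_controls `ExpressionMatrix` cohorts sharing a
#'   gene universe.
#' @param genes Module gene set (a subset of the shared universe).
#' @param n_perm Number of permutations (default 100000).
#' @param seed Integer seed.
#' @param n_modules_tested Bonferroni factor (default 1).
#' @param corr_cache Optional precomputed list with elements `cases` and
#'   `controls`: full-universe correlation matrices (reused across
#'   modules in a batch).
#' @return List of class `DispersionResult`: `dispersion`, `n_perm`,
#'   `r_exceed`, `empirical_p`, `bonferroni_p`, `module_size`.
#' @export
differential_coexpression_test <- function(expr_cases, expr_controls, genes,
                                           n_perm = 100000, seed = 1,
                                           n_modules_tested = 1,
                                           corr_cache = NULL) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  universe <- intersect(gene_ids(expr_cases), gene_ids(expr_controls))
  missing <- setdiff(genes, universe)
  if (length(missing))
    stop("module genes outside the shared universe: ",
         paste(utils::head(missing, 5), collapse = ", "))
  k <- length(genes)
  if (k > length(universe)) stop("module larger than the gene universe")
  if (is.null(corr_cache))
    corr_cache <- diffcoex_correlations(expr_cases, expr_controls,
                                        universe = universe)
  rc <- corr_cache$cases; rt <- corr_cache$controls
  d2 <- (rc[universe, universe] - rt[universe, universe])^2
  obs <- dispersion_statistic(rc, rt, genes)
  n_pairs <- k * (k - 1) / 2
  set.seed(seed)
  r_exceed <- 0L
  for (b in seq_len(n_perm)) {
    idx <- sample.int(length(universe), k)
    null_d <- sqrt(sum(d2[idx, idx]) / 2 / n_pairs)
    if (null_d > obs) r_exceed <- r_exceed + 1L
  }
  p <- empirical_pvalue(r_exceed, n_perm)
  structure(list(dispersion = obs, n_perm = n_perm, r_exceed = r_exceed,
                 empirical_p = p,
                 bonferroni_p = min(1, p * n_modules_tested),
                 module_size = k),
            class = "DispersionResult")
}

#' Precompute cohort correlation matrices for a batch of dispersion tests
#'
#' @param expr_cases,expr_controls `ExpressionMatrix` cohorts.
#' @param universe Gene universe (default: shared genes).
#' @return List with `cases` and `controls` biweight-midcorrelation
#'   matrices over the universe.
#' @export
diffcoex_correlations <- function(expr_cases, expr_controls,
                                  universe = NULL) {
  if (is.null(universe))
    universe <- intersect(gene_ids(expr_cases), gene_ids(expr_controls))
  list(cases = bicor_matrix(expr_cases$values[universe, , drop = FALSE]),
       controls = bicor_matrix(expr_controls$values[universe, , drop = FALSE]))
}
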