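# Profiling a candidate regulator gene against a module: per-gene
# Spearman correlations within each cohort, a Mann-Whitney shift test
# between cohorts' correlation distributions, and an FDR-thresholded
# core-set extraction across cohorts.

#' Correlate a regulator with module genes in one cohort
#'
#' Spearman correlation of the regulator's expression with each module
#' gene, Student-t P values, and Benjamini-Hochberg FDR computed across
#' the module's genes only (the printed denominator is the module size).
#' The regulator itself is excluded from the target list if present.
#'
#' @param expr An `ExpressionMatrix` for one cohort.
#' @param regulator Regulator gene id (non-constant).
#' @param genes Module gene ids.
#' @return A data frame of class `RegulatorProfile` with columns
#'   `gene_id`, `rho`, `p`, `fdr`.
#' @export
regulator_correlations <- function(expr, regulator, genes) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (!regulator %in% gene_ids(expr)) stop("regulator not in expression matrix")
  genes <- setdiff(intersect(genes, gene_ids(expr)), regulator)
  if (!length(genes)) stop("no module genes present")
  reg <- expr$values[regulator, ]
  if (stats::sd(reg) == 0) stop("constant regulator")
  n <- length(reg)
  rr <- rank(reg, ties.method = "average")
  rho <- apply(expr$values[genes, , drop = FALSE], 1, function(g) {
    if (stats::sd(g) == 0) return(NA_real_)
    stats::cor(rank(g, ties.method = "average"), rr)
  })
  p <- rep(1, length(rho))
  ok <- !is.na(rho)
  tval <- rho[ok] * sqrt((n - 2) / pmax(1 - rho[ok]^2, .Machine$double.eps))
  p[ok] <- 2 * stats::pt(-abs(tval), df = n - 2)
  rho[!ok] <- 0
  out <- data.frame(gene_id = genes, rho = rho, p = p,
                    fdr = stats::p.adjust(p, method = "fdr"),
                    row.names = NULL)
  class(out) <- c("RegulatorProfile", "data.frame")
  out
}

#' Shift test between two regulator profiles
#'
#' Two-sided Mann-Whitney U test comparing the regulator-gene correlation
#' distributions of two cohorts over the same gene universe; the
#' direction is the sign of the median difference (cases - controls).
#'
#' @param profile_cases,profile_controls `RegulatorProfile` objects with
#'   identical gene universes (>= 3 genes).
#' @return List with `p` and `direction` (-1, 0 or 1).
#' @export
shift_test <- function(profile_cases, profile_controls) {
  if (!setequal(profile_cases$gene_id, profile_controls$gene_id))
    stop("profiles must share the same gene universe")
  if (nrow(profile_cases) < 3) stop("need at least 3 genes")
  w <- stats::wilcox.test(profile_cases$rho, profile_controls$rho,
                          alternative = "two.sided", exact = NULL)
  list(p = w$p.value,
       direction = sign(stats::median(profile_cases$rho) -
                          stats::median(profile_controls$rho)))
}

#' Core set of consistently regulator-correlated genes
#'
#' Genes whose correlation FDR is below `fdr_threshold` in every supplied
#' cohort (optionally requiring a positive correlation in every cohort),
#' sorted by mean correlation, descending.
#'
#' @param profiles Named list of `RegulatorProfile` objects (>= 2 cohorts).
#' @param fdr_threshold FDR cut (default 0.01).
#' @param require_positive Require `rho > 0` in every cohort
#'   (default TRUE).
#' @return Character vector of gene ids (possibly empty).
#' @export
core_set <- function(profiles, fdr_threshold = 0.01, require_positive = TRUE) {
  if (length(profiles) < 2) stop("need at least 2 cohorts")
  shared <- Reduce(intersect, lapply(profiles, function(p) p$gene_id))
  if (!length(shared)) return(character(0))
  pass <- rep(TRUE, length(shared))
  mean_rho <- rep(0, length(shared))
  for (pr in profiles) {
    idx <- match(shared, pr$gene_id)
    pass <- pass & pr$fdr[idx] < fdr_threshold
    if (require_positive) pass <- pass & pr$rho[idx] > 0
    mean_rho <- mean_rho + pr$rho[idx] / length(profiles)
  }
  shared[pass][order(-mean_rho[pass])]
}
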