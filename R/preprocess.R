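# Expression and phenotype preprocessing: low-expression filtering,
# zero-replacement + log2 transform, covariate residualization, dendrogram
# outlier removal, and rank-based inverse-normal trait adjustment.

#' Filter lowly expressed genes
#'
#' Keeps a gene iff its value exceeds `threshold` in at least
#' `max(1, ceiling(min_frac * n_samples))` samples (so with 30 samples and
#' `min_frac = 0.05` a gene must pass in at least two samples).
#'
#' @param expr An `ExpressionMatrix` with unit `"fpkm"`.
#' @param threshold Expression threshold (default 1 FPKM).
#' @param min_frac Minimum fraction of samples above threshold (default 0.05).
#' @return The filtered `ExpressionMatrix`; samples unchanged.
#' @export
filter_low_expression <- function(expr, threshold = 1, min_frac = 0.05) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (expr$unit != "fpkm") stop("filtering expects FPKM-unit expression")
  if (min_frac <= 0 || min_frac > 1) stop("min_frac must be in (0, 1]")
  required <- max(1L, ceiling(min_frac * ncol(expr$values)))
  keep <- rowSums(expr$values > threshold) >= required
  if (!any(keep)) warning("no genes pass the expression filter")
  out <- expr$values[keep, , drop = FALSE]
  # empty subsets drop dimnames; restore them so the container validates
  dimnames(out) <- list(rownames(expr$values)[keep], colnames(expr$values))
  expression_matrix(out, unit = "fpkm")
}

#' Zero-replacement log2 transform
#'
#' Replaces zeros by the global minimum positive value of the matrix, then
#' applies an elementwise log2.
#'
#' @param expr An `ExpressionMatrix` with unit `"fpkm"`.
#' @return An `ExpressionMatrix` with unit `"log2"`.
#' @export
log_transform <- function(expr) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (expr$unit != "fpkm") stop("log transform expects FPKM-unit expression")
  v <- expr$values
  if (any(v < 0)) stop("negative values are not valid FPKM")
  pos <- v[v > 0]
  if (!length(pos)) stop("all-zero matrix: no positive minimum exists")
  v[v == 0] <- min(pos)
  expression_matrix(log2(v), unit = "log2")
}

# Build an intercept + covariates design matrix; errors on rank deficiency,
# naming the collinear columns via the QR pivot.
.design_matrix <- function(covariates, columns) {
  missing <- setdiff(columns, names(covariates))
  if (length(missing))
    stop("covariate columns not found: ", paste(missing, collapse = ", "))
  df <- covariates[columns]
  design <- stats::model.matrix(~ ., data = df)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    dropped <- colnames(design)[qrd$pivot[(qrd$rank + 1):ncol(design)]]
    stop("rank-deficient design; collinear columns: ",
         paste(dropped, collapse = ", "))
  }
  design
}

#' Residualize expression on covariates
#'
#' Replaces each gene's values by the residuals of an ordinary
#' least-squares fit against an intercept plus the named covariate columns
#' (factors expand to indicator contrasts dropping one level). Residuals
#' are orthogonal to every covariate column.
#'
#' @param expr An `ExpressionMatrix`.
#' @param covariates A `PhenotypeTable` covering the expression samples.
#' @param columns Covariate column names to adjust for.
#' @return An `ExpressionMatrix` with unit `"residual"`.
#' @export
residualize <- function(expr, covariates, columns) {
  stopifnot(inherits(expr, "ExpressionMatrix"),
            inherits(covariates, "PhenotypeTable"))
  samples <- sample_ids(expr)
  missing <- setdiff(samples, covariates$sample_ids)
  if (length(missing))
    stop("samples without covariate rows: ", paste(missing, collapse = ", "))
  cov <- covariates$covariates[match(samples, covariates$sample_ids), ,
                               drop = FALSE]
  design <- .design_matrix(cov, columns)
  fit <- stats::lm.fit(design, t(expr$values))
  res <- t(as.matrix(fit$residuals))
  dimnames(res) <- dimnames(expr$values)
  expression_matrix(res, unit = "residual")
}

#' Remove outlier samples by dendrogram cut
#'
#' Samples are clustered by average-linkage hierarchical clustering on the
#' Euclidean distance between expression profiles; the tree is cut at the
#' `height_quantile` of the merge-height distribution and every sample
#' outside the largest resulting cluster is removed (small clusters are
#' resolved as "everything outside the single largest cluster").
#'
#' @param expr An `ExpressionMatrix` with at least 3 samples.
#' @param height_quantile Quantile of merge heights to cut at (default 0.99).
#' @return List with `expr` (retained samples) and `removed` (dropped
#'   sample ids, possibly empty).
#' @export
remove_outlier_samples <- function(expr, height_quantile = 0.99) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (ncol(expr$values) < 3) stop("need at least 3 samples")
  if (height_quantile <= 0 || height_quantile >= 1)
    stop("height_quantile must be in (0, 1)")
  tree <- stats::hclust(stats::dist(t(expr$values)), method = "average")
  cut_h <- stats::quantile(tree$height, height_quantile, names = FALSE)
  cl <- stats::cutree(tree, h = cut_h)
  sizes <- table(cl)
  if (max(sizes) == 1L) stop("pathological tree: all samples are singletons")
  main <- as.integer(names(sizes)[which.max(sizes)])
  removed <- colnames(expr$values)[cl != main]
  keep <- expr$values[, cl == main, drop = FALSE]
  list(expr = expression_matrix(keep, unit = expr$unit), removed = removed)
}

#' Rank-based inverse-normal transform
#'
#' Maps values to `qnorm((rank - 0.5) / n)` with average ranks for ties.
#'
#' @param x Numeric vector without missing values.
#' @return Transformed vector.
#' @export
inverse_normal_transform <- function(x) {
  if (anyNA(x)) stop("missing values are not accepted")
  n <- length(x)
  stats::qnorm((rank(x, ties.method = "average") - 0.5) / n)
}

#' Normal-transform a trait and adjust it for a covariate
#'
#' The trait is replaced by its rank-based inverse-normal transform
#' followed by OLS residualization on the covariate, matching the usual
#' quantile-normalization-then-adjustment treatment of histology traits.
#'
#' @param pheno A `PhenotypeTable`.
#' @param trait Trait column name.
#' @param covariate Covariate column name.
#' @return The `PhenotypeTable` with the trait column replaced.
#' @export
adjust_trait_for_covariate <- function(pheno, trait, covariate) {
  stopifnot(inherits(pheno, "PhenotypeTable"))
  if (!trait %in% names(pheno$traits)) stop("trait not found: ", trait)
  if (!covariate %in% names(pheno$covariates))
    stop("covariate not found: ", covariate)
  y <- pheno$traits[[trait]]
  if (length(unique(y)) < 2) stop("constant trait: ", trait)
  z <- inverse_normal_transform(y)
  x <- pheno$covariates[[covariate]]
  pheno$traits[[trait]] <- stats::residuals(stats::lm(z ~ x))
  pheno
}
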