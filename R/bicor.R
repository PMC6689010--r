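# Tukey biweight midcorrelation: a robust correlation that downweights
# observations far from the median. For each vector, deviations from the
# median are scaled by 9 x MAD (MAD with the 1.4826 consistency constant);
# observations with |u| >= 1 get zero weight, others weight (1 - u^2)^2.

# Weighted deviations for one vector; NULL signals a MAD of zero (caller
# falls back to Pearson for that vector).
.bicor_transform <- function(x) {
  med <- stats::median(x)
  mad_x <- stats::mad(x)            # 1.4826 consistency constant
  if (mad_x == 0) return(NULL)
  u <- (x - med) / (9 * mad_x)
  w <- (1 - u^2)^2 * (abs(u) < 1)
  (x - med) * w
}

# Centered (Pearson-style) deviations; NA-free constant vectors give NULL.
.pearson_transform <- function(x) {
  if (stats::sd(x) == 0) return(NULL)
  x - mean(x)
}

#' Biweight midcorrelation of two vectors
#'
#' Falls back to Pearson for a vector whose MAD is zero; a vector that is
#' entirely constant (SD also zero) yields 0 with a warning, since no
#' correlation is defined.
#'
#' @param x,y Numeric vectors of equal length (>= 4), no missing values.
#' @return Correlation in `[-1, 1]`.
#' @export
bicor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 4) stop("need at least 4 observations")
  if (anyNA(x) || anyNA(y)) stop("missing values are not accepted")
  tx <- .bicor_transform(x)
  if (is.null(tx)) tx <- .pearson_transform(x)
  ty <- .bicor_transform(y)
  if (is.null(ty)) ty <- .pearson_transform(y)
  if (is.null(tx) || is.null(ty)) {
    warning("constant vector: correlation undefined, returning 0")
    return(0)
  }
  sum(tx * ty) / sqrt(sum(tx^2) * sum(ty^2))
}

#' Pairwise biweight midcorrelation matrix
#'
#' Computes the Tukey biweight midcorrelation between all gene pairs of an
#' expression matrix. Genes with zero MAD fall back to Pearson centering;
#' fully constant genes correlate 0 with everything (with a warning).
#'
#' @param expr An `ExpressionMatrix` (or a plain genes-by-samples matrix)
#'   with at least 4 samples and no missing values.
#' @return A symmetric correlation matrix with unit diagonal, gene ids as
#'   dimnames.
#' @export
bicor_matrix <- function(expr) {
  values <- if (inherits(expr, "ExpressionMatrix")) expr$values else expr
  if (ncol(values) < 4) stop("need at least 4 samples")
  if (anyNA(values)) stop("missing values are not accepted")
  n_genes <- nrow(values)
  tmat <- matrix(0, n_genes, ncol(values))
  degenerate <- logical(n_genes)
  for (i in seq_len(n_genes)) {
    tx <- .bicor_transform(values[i, ])
    if (is.null(tx)) tx <- .pearson_transform(values[i, ])
    if (is.null(tx)) { degenerate[i] <- TRUE; next }
    tmat[i, ] <- tx / sqrt(sum(tx^2))
  }
  if (any(degenerate))
    warning(sum(degenerate), " constant gene(s): correlations set to 0")
  corr <- tcrossprod(tmat)
  corr[corr > 1] <- 1
  corr[corr < -1] <- -1
  diag(corr) <- 1
  corr <- (corr + t(corr)) / 2
  dimnames(corr) <- list(rownames(values), rownames(values))
  corr
}
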