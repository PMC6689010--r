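#' Expression matrix container
#'
#' A genes-by-samples real-valued matrix tagged with its measurement unit.
#' The unit gates what operations are allowed: filtering and the log
#' transform require `"fpkm"`, correlation-based stages expect `"log2"` or
#' `"residual"` values (which must be finite).
#'
#' @param values Numeric matrix, genes in rows, samples in columns. Row and
#'   column names are the gene and sample identifiers and must be unique.
#' @param unit One of `"fpkm"`, `"log2"`, `"residual"`.
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values` and `unit`.
#' @export
expression_matrix <- function(values, unit = c("fpkm", "log2", "residual")) {
  unit <- match.arg(unit)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  # R normalizes zero-length dimnames to NULL, so only require names for
  # non-empty dimensions
  if ((nrow(values) > 0 && is.null(rownames(values))) ||
      (ncol(values) > 0 && is.null(colnames(values))))
    stop("`values` must have gene row names and sample column names")
  if (anyDuplicated(rownames(values))) stop("duplicated gene ids")
  if (anyDuplicated(colnames(values))) stop("duplicated sample ids")
  if (anyNA(values)) stop("missing values are not accepted")
  if (unit != "fpkm" && any(!is.finite(values)))
    stop("non-finite values in a ", unit, " matrix")
  structure(list(values = values, unit = unit), class = "ExpressionMatrix")
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$unit))
  invisible(x)
}

#' Gene and sample identifiers
#' @param x An `ExpressionMatrix`.
#' @return Character vector of identifiers.
#' @export
gene_ids <- function(x) rownames(x$values)

#' @rdname gene_ids
#' @export
sample_ids <- function(x) {
  if (inherits(x, "GenotypeMatrix")) colnames(x$dosage) else colnames(x$values)
}

#' Genotype matrix container
#'
#' SNPs-by-samples dosage matrix with per-SNP coordinates and optional
#' LD-block labels. Inbred-panel genotypes are binary 0/1 (two founder
#' alleles); diploid genotypes are 0/1/2 dosages. Both are treated as
#' numeric dosages downstream.
#'
#' @param dosage Numeric matrix, SNPs in rows (named), samples in columns
#'   (named); values restricted to the declared code set.
#' @param chrom Character vector of chromosome labels, one per SNP.
#' @param pos Integer vector of 1-based positions, nondecreasing within a
#'   chromosome.
#' @param block_id Optional character vector of LD-block labels (`NA` for
#'   SNPs outside any block).
#' @param ploidy `"inbred"` (codes 0/1) or `"diploid"` (codes 0/1/2).
#' @return An object of class `GenotypeMatrix`.
#' @export
genotype_matrix <- function(dosage, chrom, pos, block_id = NULL,
                            ploidy = c("inbred", "diploid")) {
  ploidy <- match.arg(ploidy)
  if (!is.matrix(dosage) || !is.numeric(dosage))
    stop("`dosage` must be a numeric matrix")
  if (is.null(rownames(dosage)) || is.null(colnames(dosage)))
    stop("`dosage` must have SNP row names and sample column names")
  p <- nrow(dosage)
  if (length(chrom) != p || length(pos) != p)
    stop("`chrom` and `pos` must have one entry per SNP")
  codes <- if (ploidy == "inbred") c(0, 1) else c(0, 1, 2)
  if (!all(dosage %in% codes))
    stop("dosage values outside the declared code set {",
         paste(codes, collapse = ","), "}")
  for (ch in unique(chrom)) {
    if (is.unsorted(pos[chrom == ch]))
      stop("positions must be nondecreasing within chromosome ", ch)
  }
  if (!is.null(block_id) && length(block_id) != p)
    stop("`block_id` must have one entry per SNP")
  structure(list(dosage = dosage, chrom = as.character(chrom),
                 pos = as.integer(pos),
                 block_id = if (is.null(block_id)) rep(NA_character_, p)
                            else as.character(block_id),
                 ploidy = ploidy),
            class = "GenotypeMatrix")
}

#' @export
print.GenotypeMatrix <- function(x, ...) {
  cat(sprintf("GenotypeMatrix: %d SNPs x %d samples (%s), %d LD blocks\n",
              nrow(x$dosage), ncol(x$dosage), x$ploidy,
              length(unique(stats::na.omit(x$block_id)))))
  invisible(x)
}

#' Phenotype table container
#'
#' Holds quantitative traits (e.g. interstitial and perivascular fibrosis)
#' and covariates (e.g. mean blood pressure, sex) for a set of samples.
#'
#' @param sample_ids Character vector of unique sample identifiers.
#' @param traits Data frame of numeric trait columns (one row per sample).
#' @param covariates Data frame of numeric or factor covariate columns.
#' @return An object of class `PhenotypeTable`.
#' @export
phenotype_table <- function(sample_ids, traits, covariates = NULL) {
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) stop("duplicated sample ids")
  traits <- as.data.frame(traits)
  if (nrow(traits) != length(sample_ids))
    stop("traits must have one row per sample")
  if (ncol(traits) > 0 && any(vapply(traits, function(col) all(is.na(col)), TRUE)))
    stop("a trait column is entirely missing")
  if (is.null(covariates)) covariates <- data.frame(row.names = seq_along(sample_ids))
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != length(sample_ids))
    stop("covariates must have one row per sample")
  rownames(traits) <- sample_ids
  rownames(covariates) <- sample_ids
  structure(list(sample_ids = sample_ids, traits = traits,
                 covariates = covariates),
            class = "PhenotypeTable")
}

#' @export
print.PhenotypeTable <- function(x, ...) {
  cat(sprintf("PhenotypeTable: %d samples, traits: %s; covariates: %s\n",
              length(x$sample_ids),
              paste(names(x$traits), collapse = ", "),
              paste(names(x$covariates), collapse = ", ")))
  invisible(x)
}

#' Module set container
#'
#' A partition of genes into labeled co-expression modules. Genes not in
#' any retained module carry the label `"unassigned"` (the analogue of the
#' grey cluster in weighted co-expression analysis); retained modules are
#' renamed `M1..Mk` by decreasing size.
#'
#' @param assignments Named character vector, gene id -> module label.
#' @param params List of detection parameters (`beta`, `merge_height`,
#'   `min_size`), kept for provenance.
#' @return An object of class `ModuleSet`.
#' @export
module_set <- function(assignments, params = list()) {
  if (is.null(names(assignments))) stop("`assignments` must be named by gene id")
  labels <- setdiff(unique(assignments), "unassigned")
  sizes <- vapply(labels, function(l) sum(assignments == l), 0L)
  structure(list(assignments = assignments,
                 module_order = labels[order(-sizes, labels)],
                 params = params),
            class = "ModuleSet")
}

#' @export
print.ModuleSet <- function(x, ...) {
  k <- length(x$module_order)
  cat(sprintf("ModuleSet: %d modules over %d genes (%d unassigned)\n",
              k, length(x$assignments),
              sum(x$assignments == "unassigned")))
  invisible(x)
}

#' Genes belonging to one module
#' @param modules A `ModuleSet`.
#' @param label Module label.
#' @return Character vector of gene ids.
#' @export
module_genes <- function(modules, label) {
  names(modules$assignments)[modules$assignments == label]
}

#' Convert a module set to a list of gene sets
#' @param modules A `ModuleSet`.
#' @return Named list of character vectors, one per module (unassigned
#'   genes are dropped).
#' @export
modules_as_gene_sets <- function(modules) {
  stats::setNames(lapply(modules$module_order, module_genes, modules = modules),
                  modules$module_order)
}

#' Genomic interval (1-based, inclusive)
#' @param chrom Chromosome label.
#' @param start,end Integer endpoints, `start <= end`.
#' @return An object of class `GenomicInterval`.
#' @export
genomic_interval <- function(chrom, start, end) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (start > end) stop("start must be <= end")
  if (start < 1) stop("1-based coordinates start at 1")
  structure(list(chrom = as.character(chrom), start = start, end = end),
            class = "GenomicInterval")
}

#' @export
print.GenomicInterval <- function(x, ...) {
  cat(sprintf("%s:%.0f..%.0f\n", x$chrom, x$start, x$end))
  invisible(x)
}
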