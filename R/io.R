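#' Read and write expression matrices as TSV
#'
#' The format is a header line of sample ids and a first column of gene
#' ids. Values round-trip at full double precision.
#'
#' @param expr An `ExpressionMatrix`.
#' @param path File path.
#' @return `write_expression_tsv` returns `path` invisibly;
#'   `read_expression_tsv` returns an `ExpressionMatrix`.
#' @export
write_expression_tsv <- function(expr, path) {
  df <- data.frame(gene_id = gene_ids(expr),
                   format(expr$values, digits = 17, trim = TRUE,
                          scientific = TRUE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @param unit Unit tag to attach on read.
#' @export
read_expression_tsv <- function(path, unit = "log2") {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2) stop("malformed expression TSV (need gene id + samples): ", path)
  values <- vapply(df[-1], as.numeric, numeric(nrow(df)))
  if (!is.matrix(values)) values <- matrix(values, nrow = nrow(df))
  bad <- which(apply(values, 1, anyNA))
  if (length(bad))
    stop("non-numeric expression value at data line ", bad[1], " of ", path)
  rownames(values) <- df[[1]]
  colnames(values) <- colnames(df)[-1]
  expression_matrix(values, unit = unit)
}

#' Read and write genotype matrices as TSV
#'
#' Columns: `snp_id`, `chrom`, `pos`, `block_id`, then one dosage column
#' per sample. `block_id` is `.` for SNPs outside any LD block.
#'
#' @param geno A `GenotypeMatrix`.
#' @param path File path.
#' @export
write_genotype_tsv <- function(geno, path) {
  df <- data.frame(snp_id = rownames(geno$dosage), chrom = geno$chrom,
                   pos = geno$pos,
                   block_id = ifelse(is.na(geno$block_id), ".", geno$block_id),
                   geno$dosage, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotype_tsv
#' @param ploidy Dosage code set declared on read.
#' @export
read_genotype_tsv <- function(path, ploidy = c("inbred", "diploid")) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  need <- c("snp_id", "chrom", "pos", "block_id")
  if (!all(need %in% colnames(df)[1:4]))
    stop("malformed genotype TSV header (expected ",
         paste(need, collapse = ", "), "): ", path)
  dos <- as.matrix(df[, -(1:4), drop = FALSE])
  storage.mode(dos) <- "double"
  rownames(dos) <- df$snp_id
  blk <- as.character(df$block_id)
  blk[blk == "."] <- NA_character_
  genotype_matrix(dos, df$chrom, df$pos, blk, ploidy = match.arg(ploidy))
}

#' Read and write phenotype tables as TSV
#'
#' First column `sample_id`; trait columns are prefixed `trait.` and
#' covariate columns `covar.` so the two groups survive a round trip.
#'
#' @param pheno A `PhenotypeTable`.
#' @param path File path.
#' @export
write_phenotype_tsv <- function(pheno, path) {
  df <- data.frame(sample_id = pheno$sample_ids, check.names = FALSE)
  for (nm in names(pheno$traits)) df[[paste0("trait.", nm)]] <- pheno$traits[[nm]]
  for (nm in names(pheno$covariates)) df[[paste0("covar.", nm)]] <- pheno$covariates[[nm]]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotype_tsv
#' @export
read_phenotype_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  if (colnames(df)[1] != "sample_id")
    stop("malformed phenotype TSV (first column must be sample_id): ", path)
  tr <- grep("^trait\\.", colnames(df), value = TRUE)
  cv <- grep("^covar\\.", colnames(df), value = TRUE)
  traits <- df[tr]
  names(traits) <- sub("^trait\\.", "", tr)
  covars <- df[cv]
  names(covars) <- sub("^covar\\.", "", cv)
  phenotype_table(df$sample_id, traits, covars)
}

#' Read and write gene sets in GMT format
#'
#' One set per line: `name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param sets Named list of character vectors.
#' @param path File path.
#' @param descriptions Optional character vector of per-set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- mapply(function(nm, desc, genes)
    paste(c(nm, desc, genes), collapse = "\t"),
    names(sets), descriptions, sets)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("malformed GMT line ", i, " of ", path)
    sets[[f[1]]] <- f[-(1:2)]
  }
  sets
}

#' Write genomic intervals as BED
#'
#' Internally intervals are 1-based inclusive; BED is 0-based half-open,
#' so `start` is decremented by one on write and restored on read.
#'
#' @param intervals List of `GenomicInterval` objects (optionally named).
#' @param path File path.
#' @export
write_bed <- function(intervals, path) {
  if (inherits(intervals, "GenomicInterval")) intervals <- list(intervals)
  nms <- names(intervals)
  if (is.null(nms)) nms <- sprintf("region%d", seq_along(intervals))
  lines <- mapply(function(iv, nm)
    sprintf("%s\t%.0f\t%.0f\t%s", iv$chrom, iv$start - 1, iv$end, nm),
    intervals, nms)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("malformed BED line ", i, " of ", path)
    iv <- genomic_interval(f[1], as.numeric(f[2]) + 1, as.numeric(f[3]))
    out[[if (length(f) >= 4) f[4] else sprintf("region%d", i)]] <- iv
  }
  out
}

#' Read and write ortholog maps as two-column TSV
#'
#' @param map Data frame with columns `gene_a`, `gene_b` (one-to-one).
#' @param path File path.
#' @export
write_ortholog_tsv <- function(map, path) {
  utils::write.table(map[, c("gene_a", "gene_b")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ortholog_tsv
#' @export
read_ortholog_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  if (ncol(df) < 2) stop("malformed ortholog TSV: ", path)
  ortholog_map(df[[1]], df[[2]])
}

#' Write planted-truth metadata as JSON
#' @param truth A `SyntheticTruth` list.
#' @param path File path.
#' @export
write_truth_json <- function(truth, path) {
  x <- unclass(truth)
  x$module_assignments <- as.list(x$module_assignments)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$module_assignments <- unlist(x$module_assignments)
  structure(x, class = "SyntheticTruth")
}
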