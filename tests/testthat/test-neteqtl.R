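mk_geno <- function(dosage, block_id, ploidy = "inbred") {
  p <- nrow(dosage)
  genotype_matrix(dosage, rep("chr1", p), seq_len(p) * 1000L, block_id,
                  ploidy = ploidy)
}

test_that("LD pruning keeps the most representative SNP per block", {
  n <- 12
  s1 <- rep(c(0, 1), each = 6)
  s2 <- s1                                   # identical to s1
  s3 <- c(s1[1:6], rev(s1[7:12]))            # half agrees
  d <- rbind(s1 = s1, s2 = s2, s3 = s3)
  colnames(d) <- paste0("x", 1:n)
  g <- mk_geno(d, rep("B1", 3))
  pr <- prune_ld_blocks(g)
  expect_equal(rownames(pr$dosage), "s1")    # tie s1/s2 broken by order
  # all identical: first kept
  d2 <- rbind(a = s1, b = s1, c = s1); colnames(d2) <- paste0("x", 1:n)
  expect_equal(rownames(prune_ld_blocks(mk_geno(d2, rep("B1", 3)))$dosage),
               "a")
  # singleton blocks and blockless SNPs pass through; size invariant holds
  d3 <- rbind(d, solo = s3, free1 = s1, free2 = s3)
  colnames(d3) <- paste0("x", 1:n)
  g3 <- mk_geno(d3, c("B1", "B1", "B1", "B2", NA, NA))
  pr3 <- prune_ld_blocks(g3)
  expect_equal(nrow(pr3$dosage), 2 + 2)      # blocks + blockless
  expect_true(all(c("solo", "free1", "free2") %in% rownames(pr3$dosage)))
})

test_that("an exact predictor is found and unrelated ones stay near prior", {
  set.seed(1)
  n <- 40; p <- 10
  X <- qr.Q(qr(matrix(rnorm(n * p), n, p)))   # orthogonal columns
  y <- X[, 3]
  mppi <- spike_slab_mppi(y, X, e_pg = 2, n_iter = 20000, seed = 2)
  expect_gt(mppi[3], 0.99)
  expect_true(all(mppi[-3] < 0.05))
  ex <- exact_mppi_enumeration(y, X[, 1:8], e_pg = 2)
  expect_gt(ex[3], 0.99)
})

test_that("sampler matches exact enumeration within 0.02", {
  set.seed(3)
  for (s in 1:3) {
    n <- 50; p <- 6
    X <- matrix(rbinom(n * p, 1, 0.4), n, p)
    y <- 0.7 * X[, 2] - 0.5 * X[, 5] + rnorm(n)
    mc <- spike_slab_mppi(y, X, n_iter = 50000, seed = 10 + s)
    ex <- exact_mppi_enumeration(y, X)
    expect_lt(max(abs(mc - ex)), 0.02)
  }
})

test_that("null responses keep every inclusion probability shrunk", {
  prior <- 2 / 6
  # the weakest possible single-predictor likelihood ratio under the
  # unit-information slab is (1 + n)^(-1/2), which bounds a null
  # predictor's posterior odds below prior odds x that factor
  floor_mppi <- function(n) {
    lr <- (1 + n)^(-1 / 2)
    o <- prior / (1 - prior) * lr
    o / (1 + o)
  }
  worst_lo <- Inf
  all_mppi <- c()
  for (s in 1:20) {
    set.seed(600 + s)
    X <- matrix(rbinom(50 * 6, 1, 0.3), 50, 6)
    y <- rnorm(50)
    ex <- exact_mppi_enumeration(y, X)
    worst_lo <- min(worst_lo, min(ex))
    all_mppi <- c(all_mppi, as.numeric(ex))
  }
  expect_gte(worst_lo, 0.95 * floor_mppi(50))
  expect_lte(max(all_mppi), min(1, 10 * prior))
  # the bulk of null inclusion probabilities stays near the prior
  expect_lt(median(all_mppi), 2 * prior)
})

test_that("duplicated predictors split the inclusion mass", {
  set.seed(4)
  n <- 60
  x <- rbinom(n, 1, 0.5)
  y <- x + rnorm(n, sd = 0.4)
  single <- exact_mppi_enumeration(y, cbind(x), e_pg = 0.5)
  dup <- exact_mppi_enumeration(y, cbind(x, x), e_pg = 1)
  # same per-predictor prior (0.5); duplicates share the posterior mass
  expect_equal(dup[1], dup[2], tolerance = 1e-10)
  p_any <- 1 - (1 - single[1])                # inclusion of the signal alone
  expect_equal(dup[1] + dup[2] - 0, p_any, tolerance = 0.12)
  expect_error(exact_mppi_enumeration(y, matrix(0, n, 16)), "p <= 15")
})

test_that("mppi is invariant to positive rescaling of a genotype column", {
  set.seed(5)
  n <- 40
  X <- matrix(rbinom(n * 5, 2, 0.3), n, 5)
  y <- X[, 1] * 0.8 + rnorm(n)
  m1 <- spike_slab_mppi(y, X, n_iter = 5000, seed = 6)
  X2 <- X; X2[, 1] <- X2[, 1] * 7.5
  m2 <- spike_slab_mppi(y, X2, n_iter = 5000, seed = 6)
  expect_equal(as.numeric(m1), as.numeric(m2), tolerance = 1e-12)
  expect_error(spike_slab_mppi(y, X[, 0, drop = FALSE]), "predictors")
  expect_error(spike_slab_mppi(c(y[-1], NA), X), "non-finite")
})

test_that("Bayes-factor conversion follows the posterior/prior odds ratio", {
  expect_equal(signif(2 / 1384, 2), 0.0014)   # printed genome-wide prior
  expect_equal(mppi_to_bf(0.5, 2 / 1384), 691, tolerance = 0.5)
  expect_equal(mppi_to_bf(2 / 1384, 2 / 1384), 1, tolerance = 1e-12)
  # strictly increasing in mppi
  bfs <- mppi_to_bf(seq(0.01, 0.99, by = 0.01), 0.02)
  expect_true(all(diff(bfs) > 0))
  expect_error(mppi_to_bf(1, 0.5), "mppi")
  expect_error(mppi_to_bf(0.5, 0), "prior_pi")
})

test_that("a single-gene module's median BF is that gene's BF", {
  g <- generate_genotypes(30, 10, 1, seed = 7)
  pe <- generate_panel_expression(g, 20, c(5), hotspot_block = "B2",
                                  seed = 8)
  nq <- network_eqtl_map(pe$expr, "gene0001", g, n_iter = 2000, seed = 9)
  expect_equal(nq$summary$median_bf, unname(nq$bf[1, ]))
  expect_equal(nq$prior_pi, 2 / 10)
})

test_that("a null effect calls no locus", {
  for (s in 1:5) {
    g <- generate_genotypes(30, 30, 1, seed = 700 + s)
    pe <- generate_panel_expression(g, 40, c(20), hotspot_block = "B1",
                                    hotspot_effect = 0, seed = 800 + s)
    mg <- names(pe$truth$module_assignments)[
      pe$truth$module_assignments == "P1"]
    nq <- network_eqtl_map(pe$expr, mg, g, n_iter = 1500, seed = s)
    expect_false(any(nq$summary$called))
  }
})

test_that("the syntenic window reproduces the printed human region", {
  block <- genomic_interval("chr19", 20000000, 26220000)
  center <- 20000000 + (26220000 - 20000000) / 2
  genes_src <- data.frame(gene_id = c("far", "near"), chrom = "chr19",
                          start = c(1e6, center - 40000),
                          end = c(1.1e6, center + 20000))
  map <- ortholog_map(c("far", "near"), c("FAR_HS", "NEAR_HS"))
  # ortholog gene centered at 69,415,969
  genes_tgt <- data.frame(gene_id = c("FAR_HS", "NEAR_HS"),
                          chrom = c("chr2", "chr16"),
                          start = c(5e6, 69405969), end = c(6e6, 69425969))
  win <- syntenic_window(block, genes_src, map, genes_tgt, window_mb = 10)
  expect_equal(win$chrom, "chr16")
  expect_equal(win$start, 64415969)
  expect_equal(win$end, 74415969)
  expect_equal(attr(win, "anchor_gene_tgt"), "NEAR_HS")
  # degenerate zero-width window collapses to the gene center
  win0 <- syntenic_window(block, genes_src, map, genes_tgt, window_mb = 0)
  expect_equal(win0$start, win0$end)
  expect_equal(win0$start, 69415969)
})

test_that("equidistant anchor genes resolve to the smaller start", {
  block <- genomic_interval("chr1", 1000000, 1000000)
  genes_src <- data.frame(gene_id = c("left", "right"), chrom = "chr1",
                          start = c(994000, 1004000),
                          end = c(998000, 1008000))   # centers at +-4 kb
  map <- ortholog_map(c("left", "right"), c("L", "R"))
  genes_tgt <- data.frame(gene_id = c("L", "R"), chrom = "chrX",
                          start = c(100000, 900000), end = c(110000, 910000))
  win <- syntenic_window(block, genes_src, map, genes_tgt, window_mb = 0.01)
  expect_equal(attr(win, "anchor_gene_src"), "left")
  # genes without orthologs are skipped in favor of mappable ones
  map2 <- ortholog_map("right", "R")
  win2 <- syntenic_window(block, genes_src, map2, genes_tgt, 0.01)
  expect_equal(attr(win2, "anchor_gene_src"), "right")
  expect_error(syntenic_window(block, genes_src,
                               ortholog_map("other", "O"), genes_tgt, 1),
               "no mappable")
})

test_that("Kruskal-Wallis matches a from-scratch rank computation", {
  y <- c(1, 2, 3, 4, 5, 6)
  grp <- rep(c(0, 1), each = 3)
  kw <- kruskal_by_genotype(y, grp)
  # from-scratch: H = 12/(N(N+1)) * sum n_i (Rbar_i - Rbar)^2
  r <- rank(y)
  H <- 12 / (6 * 7) * (3 * (mean(r[1:3]) - 3.5)^2 + 3 * (mean(r[4:6]) - 3.5)^2)
  expect_equal(kw$statistic, H, tolerance = 1e-12)
  expect_equal(H, 3.857, tolerance = 1e-3)
  # constant isoform: H = 0, P = 1
  kw0 <- kruskal_by_genotype(rep(2, 6), grp)
  expect_equal(kw0$statistic, 0)
  expect_equal(kw0$p.value, 1)
  # groups below 2 samples are dropped
  expect_warning(kw1 <- kruskal_by_genotype(c(1, 2, 3, 4, 9),
                                            c(0, 0, 1, 1, 2)), "dropping")
  expect_false(kw1$flagged)
})

test_that("cis mapping flags only the isoform loaded on the planted SNP", {
  hits <- 0L
  for (s in 1:10) {
    g <- generate_genotypes(60, 8, 2, seed = 900 + s)
    d <- g$dosage[g$block_id == "B3", ][1, ]
    set.seed(950 + s)
    v <- rbind(isoA = 1.5 * d + rnorm(60, sd = 0.5),
               isoB = rnorm(60),
               isoC = rnorm(60))
    colnames(v) <- colnames(g$dosage)
    e <- expression_matrix(v, unit = "log2")
    win <- genomic_interval("chr1", 1, max(g$pos))
    res <- cis_isoform_eqtl(e, g, win, n_iter = 2000, seed = s)
    fa <- res$kw$fdr[res$kw$isoform == "isoA"]
    fo <- res$kw$fdr[res$kw$isoform != "isoA"]
    if (fa < 0.05 && all(fo >= 0.05)) hits <- hits + 1L
  }
  expect_gte(hits, 9)
})
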