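test_that("TOM reproduces hand-computed values and bounds", {
  # triangle with all adjacencies 0.5: TOM_12 = (0.25 + 0.5)/(1 + 1 - 0.5)
  a <- matrix(0.5, 3, 3); diag(a) <- 1
  tom <- tom_similarity(a)
  expect_equal(tom[1, 2], 0.5, tolerance = 1e-12)
  # two nodes with a = 1 and no other edges -> TOM = 1
  a2 <- diag(4); a2[1, 2] <- a2[2, 1] <- 1
  expect_equal(tom_similarity(a2)[1, 2], 1)
  # no edge and no shared neighbors -> TOM = 0
  expect_equal(tom_similarity(a2)[3, 4], 0)
  expect_error(tom_similarity(matrix(c(0, -0.1, -0.1, 0), 2, 2)),
               "nonnegative")
})

test_that("TOM respects its lower bound and block structure", {
  set.seed(1)
  a <- matrix(runif(100, 0, 0.9), 10, 10)
  a <- (a + t(a)) / 2; diag(a) <- 0
  tom <- tom_similarity(a)
  expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
  k <- rowSums(a)
  lower <- a * pmin(1 / (outer(k, k, pmin) + 1 - a), 1)
  expect_true(all(tom + 1e-12 >= lower))
  # identity-block adjacency maps to itself
  blk <- matrix(0, 6, 6); blk[1:3, 1:3] <- 1; blk[4:6, 4:6] <- 1
  diag(blk) <- 0
  tb <- tom_similarity(blk)
  expect_equal(tb[1, 2], 1); expect_equal(tb[1, 4], 0)
})

test_that("the soft-threshold rule picks highest connectivity above the cut", {
  d <- data.frame(beta = c(2, 4, 6),
                  scale_free_r2 = c(0.5, 0.85, 0.9),
                  mean_connectivity = c(20, 10, 4))
  sel <- select_beta(d, 0.8)
  expect_equal(sel$beta, 4)
  expect_false(sel$flagged)
  # all below the cut: fall back to the best fit, flagged
  d2 <- transform(d, scale_free_r2 = c(0.5, 0.6, 0.7))
  sel2 <- select_beta(d2, 0.8)
  expect_equal(sel2$beta, 6)
  expect_true(sel2$flagged)
  # tie on mean connectivity: smallest beta
  d3 <- data.frame(beta = c(3, 5), scale_free_r2 = c(0.9, 0.9),
                   mean_connectivity = c(7, 7))
  expect_equal(select_beta(d3, 0.8)$beta, 3)
  expect_error(pick_soft_threshold(diag(3), integer(0)), "non-empty")
})

test_that("a planted single-module network reaches a scale-free fit", {
  cc <- generate_case_control(100, 100, 50, 0.8, 0.8, 150, seed = 1)
  corr <- bicor_matrix(cc$cases)
  pick <- pick_soft_threshold(corr, 1:12)
  expect_true(any(pick$diagnostics$scale_free_r2 > 0.8, na.rm = TRUE))
  expect_false(pick$flagged)
})

test_that("module eigengene matches an independent PCA and orients itself", {
  e <- noise_expr(3, 15, seed = 2)
  eg <- module_eigengene(e, gene_ids(e))
  # independent route: principal components of the standardized genes
  pc <- prcomp(t(scale(t(e$values))), center = FALSE, scale. = FALSE)
  v <- pc$rotation[, 1] / sqrt(sum(pc$rotation[, 1]^2))
  expect_equal(abs(unname(eg$loadings)), abs(unname(v)), tolerance = 1e-10)
  expect_equal(sqrt(sum(eg$loadings^2)), 1, tolerance = 1e-12)
  # identical genes: eigengene correlates 1 with each member
  ident <- expression_matrix(matrix(rep(rnorm(15), 3), 3, 15, byrow = TRUE,
                                    dimnames = dimnames(e$values)),
                             unit = "log2")
  egi <- module_eigengene(ident, gene_ids(ident))
  expect_equal(cor(egi$loadings, ident$values[1, ]), 1, tolerance = 1e-10)
  # flipping all member genes preserves the positive-orientation rule
  flip <- expression_matrix(-e$values, unit = "log2")
  egf <- module_eigengene(flip, gene_ids(flip))
  zc <- t(scale(t(flip$values)))
  expect_gte(mean(zc %*% egf$loadings), 0)
  expect_error(module_eigengene(e, "g001"), "2 module genes")
})

test_that("planted modules are recovered and merging obeys the threshold", {
  cc <- two_module_fixture(seed = 11)
  corr <- bicor_matrix(cc$cases)
  tom <- tom_similarity(abs(corr)^6)
  det <- detect_modules(tom, cc$cases, min_size = 30, merge_height = 0.25,
                        beta = 6)
  expect_equal(length(det$modules$module_order), 2)
  truth <- cc$truth$module_assignments
  for (pl in c("P1", "P2")) {
    planted <- names(truth)[truth == pl]
    found <- det$modules$assignments[planted]
    expect_gte(max(table(found)) / length(planted), 0.95)
  }
  # merge_height = 0: identical result to no merging
  det0 <- detect_modules(tom, cc$cases, min_size = 30, merge_height = 0)
  expect_gte(length(det0$modules$module_order), 2)
  # two blocks driven by one factor collapse into one module at 0.25
  set.seed(12)
  n <- 100; f <- rnorm(n)
  v <- rbind(matrix(sqrt(0.8) * rep(f, each = 40), 40, n) +
               sqrt(0.2) * matrix(rnorm(40 * n), 40, n),
             matrix(sqrt(0.8) * rep(f, each = 40), 40, n) +
               sqrt(0.2) * matrix(rnorm(40 * n), 40, n),
             matrix(rnorm(60 * n), 60, n))
  dimnames(v) <- list(sprintf("g%03d", 1:140), sprintf("s%03d", 1:n))
  ev <- expression_matrix(v, unit = "log2")
  tom1 <- tom_similarity(abs(bicor_matrix(ev))^6)
  det1 <- detect_modules(tom1, ev, min_size = 30, merge_height = 0.25)
  expect_equal(length(det1$modules$module_order), 1)
  expect_gte(sum(det1$modules$assignments == "M1"), 76)
})

test_that("module detection is equivariant under gene permutation", {
  cc <- two_module_fixture(seed = 13)
  perm <- sample(nrow(cc$cases$values))
  ep <- expression_matrix(cc$cases$values[perm, ], unit = "log2")
  inf1 <- infer_modules(cc$cases, beta = 6)
  inf2 <- infer_modules(ep, beta = 6)
  a1 <- inf1$modules$assignments
  a2 <- inf2$modules$assignments[names(a1)]
  expect_equal(ari(a1, a2), 1)
})

test_that("an all-noise matrix yields no modules, with a warning", {
  e <- noise_expr(60, 40, seed = 14)
  tom <- tom_similarity(abs(bicor_matrix(e))^6)
  expect_warning(det <- detect_modules(tom, e, min_size = 30), "unassigned")
  expect_equal(length(det$modules$module_order), 0)
  expect_true(all(det$modules$assignments == "unassigned"))
})
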