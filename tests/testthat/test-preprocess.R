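fpkm_fixture <- function(values) {
  expression_matrix(values, unit = "fpkm")
}

test_that("expression filter applies the minimum-sample rule", {
  # 30 samples at min_frac 0.05 -> required count 2
  set.seed(1)
  v <- matrix(runif(5 * 30, 2, 10), 5, 30,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:30)))
  v[1, ] <- 0                      # never above threshold
  v[2, ] <- 0; v[2, 1] <- 5       # above in exactly 1 sample
  v[3, ] <- 0; v[3, 1:2] <- 5     # above in exactly 2 samples
  f <- filter_low_expression(fpkm_fixture(v), threshold = 1, min_frac = 0.05)
  expect_setequal(gene_ids(f), c("g3", "g4", "g5"))
  # toy 3x4: gene above threshold in 1 of 4 samples needs 2 at min_frac 0.5
  v2 <- matrix(c(5, 5, 5, 5,
                 2, 0, 0, 0,
                 0, 0, 0, 0), 3, 4, byrow = TRUE,
               dimnames = list(c("keep", "drop1", "drop0"), paste0("s", 1:4)))
  f2 <- filter_low_expression(fpkm_fixture(v2), 1, 0.5)
  expect_equal(gene_ids(f2), "keep")
  # idempotence
  f3 <- filter_low_expression(f2, 1, 0.5)
  expect_identical(f3$values, f2$values)
  expect_warning(filter_low_expression(fpkm_fixture(v2 * 0), 1, 0.5),
                 "no genes")
})

test_that("log transform replaces zeros by the minimum positive value", {
  v <- matrix(c(0, 2, 4, 8), 2, 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  lt <- log_transform(fpkm_fixture(v))
  expect_equal(unname(lt$values), matrix(c(1, 1, 2, 3), 2, 2, byrow = TRUE))
  expect_equal(lt$unit, "log2")
  ones <- fpkm_fixture(matrix(1, 2, 2, dimnames = dimnames(v)))
  expect_true(all(log_transform(ones)$values == 0))
  neg <- v; neg[1, 1] <- -1
  expect_error(log_transform(fpkm_fixture(neg)), "negative")
  expect_error(log_transform(fpkm_fixture(v * 0)), "all-zero")
})

test_that("residualization is an orthogonal projection", {
  set.seed(2)
  n <- 20
  covs <- data.frame(bp = rnorm(n), sex = factor(rep(c("m", "f"), n / 2)))
  pheno <- phenotype_table(paste0("s", 1:n), data.frame(dummy = rnorm(n)), covs)
  v <- matrix(rnorm(5 * n), 5, n,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:n)))
  v[1, ] <- covs$bp                               # gene equal to a covariate
  e <- expression_matrix(v, unit = "log2")
  r <- residualize(e, pheno, c("bp", "sex"))
  expect_equal(r$unit, "residual")
  expect_true(all(abs(r$values[1, ]) < 1e-10))
  # orthogonality to the design
  design <- model.matrix(~ bp + sex, covs)
  ip <- abs(crossprod(design, t(r$values)))
  expect_true(all(ip < 1e-8 * sqrt(colSums(design^2)) %o%
                    sqrt(rowSums(r$values^2) + 1e-300)))
  # projection: applying twice changes nothing
  r2 <- residualize(r, pheno, c("bp", "sex"))
  expect_equal(r2$values, r$values, tolerance = 1e-10)
})

test_that("residualization matches closed-form OLS on four points", {
  x <- c(1, 2, 3, 4)
  gene <- 2 * x + c(1, -1, 1, -1)
  # normal equations by hand: regress gene on [1, x]
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% gene)
  expected <- as.numeric(gene - X %*% beta)
  pheno <- phenotype_table(paste0("s", 1:4), data.frame(t = 1:4),
                           data.frame(x = x))
  e <- expression_matrix(matrix(gene, 1, 4,
                                dimnames = list("g1", paste0("s", 1:4))),
                         unit = "log2")
  r <- residualize(e, pheno, "x")
  expect_equal(unname(r$values[1, ]), expected, tolerance = 1e-12)
})

test_that("rank-deficient designs are rejected with the collinear column", {
  n <- 10
  covs <- data.frame(a = 1:n, b = 2 * (1:n))
  pheno <- phenotype_table(paste0("s", 1:n), data.frame(t = rnorm(n)), covs)
  e <- noise_expr(3, n)
  colnames(e$values) <- paste0("s", 1:n)
  expect_error(residualize(e, pheno, c("a", "b")), "collinear.*b")
})

test_that("a grossly displaced sample is removed by the dendrogram cut", {
  set.seed(7)
  v <- matrix(rnorm(50 * 20), 50, 20,
              dimnames = list(paste0("g", 1:50), paste0("s", 1:20)))
  v[, 13] <- v[, 13] + 100
  out <- remove_outlier_samples(expression_matrix(v, unit = "log2"), 0.99)
  expect_equal(out$removed, "s13")
  expect_equal(ncol(out$expr$values), 19)
})

test_that("the cut never removes more than half of homogeneous samples", {
  for (s in 1:8) {
    e <- noise_expr(40, 24, seed = 100 + s)
    out <- remove_outlier_samples(e, 0.99)
    expect_lte(length(out$removed), 12)
  }
  expect_error(remove_outlier_samples(noise_expr(10, 24), 1.2), "quantile")
  expect_error(remove_outlier_samples(noise_expr(10, 2), 0.99), "3 samples")
})

test_that("inverse-normal transform matches hand quantiles and keeps order", {
  x <- c(3, 1, 4, 2)
  expect_equal(inverse_normal_transform(x),
               qnorm((c(3, 1, 4, 2) - 0.5) / 4))
  set.seed(3)
  y <- rnorm(25)
  expect_equal(order(inverse_normal_transform(y)), order(y))
})

test_that("trait adjustment normalizes then removes the covariate", {
  set.seed(4)
  n <- 30
  bp <- rnorm(n)
  tr <- 2 * bp + rnorm(n, sd = 0.5)
  pheno <- phenotype_table(paste0("s", 1:n),
                           data.frame(fib = tr),
                           data.frame(bp = bp))
  adj <- adjust_trait_for_covariate(pheno, "fib", "bp")
  out <- adj$traits$fib
  expect_equal(mean(out), 0, tolerance = 1e-10)
  expect_lt(abs(sum(out * bp)), 1e-8 * sqrt(sum(out^2)) * sqrt(sum(bp^2)))
  # trait equal to covariate: residual collapses toward zero
  pheno2 <- phenotype_table(paste0("s", 1:n), data.frame(fib = bp),
                            data.frame(bp = bp))
  adj2 <- adjust_trait_for_covariate(pheno2, "fib", "bp")
  expect_lt(sd(adj2$traits$fib), 0.2 * sd(inverse_normal_transform(bp)))
  pheno3 <- phenotype_table(paste0("s", 1:n), data.frame(fib = rep(1, n)),
                            data.frame(bp = bp))
  expect_error(adjust_trait_for_covariate(pheno3, "fib", "bp"), "constant")
})
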