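# Shared fixtures and small independent oracles used across test files.
# All fixtures are generated in code under fixed seeds.

# adjusted Rand index between two labelings (mclust's implementation,
# used as the independent scorer for module recovery)
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# a small expression matrix of iid Gaussian noise
noise_expr <- function(n_genes, n_samples, seed = 1, unit = "log2") {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%03d", seq_len(n_samples))))
  expression_matrix(m, unit = unit)
}

# independent transcription of the biweight midcorrelation definition,
# kept deliberately naive (used as the formula oracle for bicor())
bicor_oracle <- function(x, y) {
  wdev <- function(v) {
    u <- (v - median(v)) / (9 * mad(v))
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    (v - median(v)) * w
  }
  a <- wdev(x); b <- wdev(y)
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

# brute-force classic GSEA running sum over an explicit gene list
es_oracle <- function(ordered_genes, set) {
  N <- length(ordered_genes)
  hit <- ordered_genes %in% set
  nh <- sum(hit)
  rs <- cumsum(ifelse(hit, 1 / nh, -1 / (N - nh)))
  mx <- max(rs); mn <- min(rs)
  if (mx >= -mn - 1e-9) mx else mn
}

# observed ES as the package computes it, from a ranked data frame
package_es <- function(ranked_genes, set) {
  fibronet:::.es_from_positions(match(intersect(set, ranked_genes),
                                      ranked_genes), length(ranked_genes))
}

# planted two-module case/control fixture (shared by coexnet tests)
two_module_fixture <- function(seed, n = 100, rho = 0.8) {
  generate_case_control(n, n, c(50, 50), rho, rho, 100, seed = seed)
}
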