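---
title: "Methods: co-expression networks, differential co-expression and network-eQTL mapping in fibronet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-expression networks, differential co-expression and network-eQTL mapping in fibronet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibronet)
```

# Overview

fibronet implements a systems-genetics workflow for tissue transcriptomes:
it infers robust gene co-expression modules, asks whether a module tracks a
quantitative disease trait (fibrosis histology, in the motivating
application), whether it is conserved between a model-organism panel and a
human cohort, whether its co-expression differs between patients and
controls, and — the centerpiece — whether a genetic locus jointly controls
the module's expression (a *trans*-acting network-eQTL), summarized by
Bayes factors. A synthetic-data generator with planted ground truth makes
every stage testable end to end.

This vignette records the statistical model behind each stage, the
parameters that matter, and the design decisions taken where more than one
reasonable implementation exists.

# Co-expression module inference

**Correlation.** Pairwise gene similarity is the Tukey biweight
midcorrelation. For a vector $x$, deviations from the median are scaled by
$9 \times \mathrm{MAD}(x)$ (MAD with the usual 1.4826 consistency
constant); observations with $|u| \ge 1$ get zero weight, the rest weight
$(1-u^2)^2$; the midcorrelation is the normalized cross-product of the
weighted deviations. This downweights single-sample outliers that can
dominate Pearson correlation at panel-scale $n$. A gene with zero MAD
(majority-constant) falls back to Pearson centering; an entirely constant
gene correlates 0 with everything, with a warning. On clean Gaussian data
bicor tracks Pearson closely but not to numerical identity — the weights
are never exactly uniform on a finite sample — and the test suite asserts
agreement within 0.02 at $n = 200$.

**Adjacency and soft threshold.** The network is *unsigned*:
$a_{ij} = |\mathrm{bicor}_{ij}|^\beta$. The sign convention is not a free
choice downstream (dispersion and conservation only use memberships), and
unsigned is the default of the weighted co-expression framework this stage
follows. $\beta$ is chosen by scale-free fit: connectivities
$k_i = \sum_{j \ne i} a_{ij}$ are binned into 10 *equal-width* bins,
zero-count bins dropped, and $R^2$ is taken from regressing
$\log_{10} p(k)$ on $\log_{10}$ of the bin-mean connectivity. Among
candidate $\beta$ with $R^2 > 0.8$ the one with the highest mean
connectivity wins (ties: smallest $\beta$); if none qualifies the best-fit
$\beta$ is returned flagged. Equal-width binning is deliberate: with
equal-count bins $p(k)$ is constant by construction and the fit is
meaningless.

**Topological overlap and clustering.** The clustering dissimilarity is
$1 - \mathrm{TOM}$ with
$\mathrm{TOM}_{ij} = (\sum_u a_{iu}a_{uj} + a_{ij}) / (\min(k_i,k_j) + 1 - a_{ij})$.
Genes are clustered by average linkage and the tree is cut *statically at
an absolute height* (`cut_height`, default 0.99 on the $1-\mathrm{TOM}$
scale). We originally prototyped a cut at a quantile of the merge-height
distribution, but on planted fixtures the merge heights of the unconnected
background concentrate immediately below 1.0, so any high quantile lands
among the background merges and fuses modules with noise (adjusted Rand
index against planted labels near 0). An absolute cut just below the
dissimilarity of unconnected pairs separates planted modules reliably
(ARI ≥ 0.97 across seeds in the acceptance suite) while background genes
fragment into sub-`min_size` clusters and land in `"unassigned"`. The
dynamic hybrid tree cut of the reference implementation is intentionally
not reimplemented; the static cut is a declared substitution, adequate for
equicorrelated module structure.

**Eigengenes and merging.** A module eigengene is the first right-singular
vector of the gene-standardized submatrix, unit norm, sign-oriented to
nonnegative mean correlation with member genes. Module pairs whose
eigengene dissimilarity $1 - \mathrm{cor}$ falls below `merge_height`
(default 0.25) merge iteratively, closest pair first; retained modules are
relabeled `M1..Mk` by decreasing size. `min_size` defaults to 30.

# Module-trait association (pre-ranked GSEA)

Genes are ranked by the Student-$t$ $P$ value of the Spearman correlation
between expression and the (inverse-normal transformed, covariate-adjusted)
trait, with the *largest* $P$ first. With that orientation a
trait-associated module enriches at the *bottom* of the list and shows a
significant **negative** normalized enrichment score; the association call
is `fdr_q < 0.05` with NES < 0. The enrichment statistic is the classic
(unweighted) running sum: hits add $1/N_h$, misses subtract $1/(N-N_h)$,
ES is the signed maximum deviation. Exact $\pm$ ties between the maximal
positive and negative deviations resolve to the positive one, with a
$10^{-9}$ tolerance so that last-ulp rounding of the rational increments
cannot flip the sign.

The null is gene-label permutation (the only option in pre-ranked mode):
`n_perm` random same-size sets, shared across sets of equal size.
NES divides ES by the mean magnitude of same-sign null ES; the FDR $q$
follows the positive/negative-tail normalized procedure of the reference
method, with monotonicity in $|NES|$ enforced within each sign class.
Default `n_perm` is 10,000; tests and the demo use 300–1,000 for runtime.

# Cross-species conservation

Modules from two species are restricted to a background of one-to-one
orthologs expressed in both tissues; every module pair is tested by a
one-sided (enrichment) Fisher exact test on the $2\times2$ overlap table
over that background, and $P$ values are adjusted by Benjamini–Yekutieli
across all pairs (valid under the arbitrary dependence created by shared
memberships). The suite verifies FET against the closed-form
hypergeometric tail to $10^{-12}$ and the B&Y inflation identity.

# Differential co-expression (dispersion test)

For a module $S$ with cohort correlation matrices $r^{case}, r^{ctrl}$
(biweight midcorrelation on each cohort),

$$D(S) = \sqrt{\tfrac{1}{\binom{|S|}{2}} \sum_{i<j \in S}
        (r^{case}_{ij} - r^{ctrl}_{ij})^2}.$$

The root-mean-square form over raw pairwise correlations is pinned here
explicitly; alternatives (Fisher-z, pair weights) are not used. The null
draws `n_perm` gene sets of size $|S|$ without replacement from the
post-filter expressed-gene universe; $P = (r+1)/(n+1)$ with $r$ the count
of null dispersions *strictly* greater than the observed (ties count as
non-exceeding; conservative and negligible at $10^5$ permutations, the
default, which yields the minimum attainable $P = 10^{-5}$). Bonferroni
correction uses the number of modules in the batch. Cohort correlation
matrices are computed once per batch and cached (dense, appropriate to the
≤ 5,000-gene scale this package targets).

Type-I calibration is checked on *fully exchangeable* null cohorts
(planted correlation 0 everywhere): there the observed set is
distributionally a uniform draw and the empirical $P$ is exactly uniform;
the acceptance suite requires a 0.05-level rejection rate of 0.05 ± 0.02
over 500 replicates. With equal but nonzero planted correlation the tested
module is no longer exchangeable with mostly-background null sets and the
test becomes mildly conservative — a property of the published procedure,
not of this implementation.

# Network-eQTL mapping

**LD pruning.** Within each LD block the SNP with the highest mean
Spearman correlation to the rest of the block is kept (ties: input order);
blockless SNPs pass through and are appended. For strain-panel genotypes,
SNPs within a block share a strain-distribution pattern, so any
representative is equivalent and the first wins.

**Per-gene variable selection.** Each module gene's expression $y$ is
regressed on all pruned SNP dosages $X$ (internally standardized) under
spike-and-slab selection: inclusion indicators
$\gamma_j \sim \mathrm{Bernoulli}(\pi)$ with $\pi = E(p_g)/p$, where
$E(p_g) = 2$ expected control points per gene and $p$ is the number of
SNPs tested (so $p = 1384$ gives $\pi = 1.4\times10^{-3}$). Included
coefficients carry a Zellner $g$-prior with $g = n$ (unit-information);
integrating coefficients and the residual variance gives the closed-form
marginal likelihood

$$m(\gamma) \propto (1+g)^{-q_\gamma/2}
  \left[y^\top y - \tfrac{g}{1+g}\,\mathrm{SSR}_\gamma\right]^{-(n-1)/2},$$

which a Metropolis–Hastings chain explores with add/delete/swap proposals
(equal probability, single chain, burn-in 20%, seeds exposed; marginal
likelihoods cached per visited model; rank-deficient submodels fall back
to a QR projection). The MPPI of SNP $j$ is its post-burn-in inclusion
frequency. The closed form is what makes an *exact* small-$p$ reference
possible: `exact_mppi_enumeration()` sums the same marginal likelihood
over all $2^p$ models, and the acceptance suite requires sampler vs
enumeration agreement within 0.02 per predictor at $p = 8$ and 50,000
iterations. A published hierarchical sampler with cross-response hotspot
sharing exists for this problem; it is deliberately replaced by
independent per-response selection with the same prior and the same
downstream summaries, because the shared prior, the Bayes-factor
conversion and the median-BF summary are fully specified while the
sampler internals are not. The hotspot-sharing tier is out of scope.

**Bayes factors and locus calling.** Per gene-SNP pair,
$\mathrm{BF} = [\mathrm{MPPI}/(1-\mathrm{MPPI})]\,/\,[\pi/(1-\pi)]$, with
MPPI capped at $1 - 1/(2\,n_{iter})$ before conversion (caps are flagged);
$\mathrm{BF}=1$ means the data moved nothing. A SNP is called a network
regulatory locus when the **median BF across module genes exceeds 100**;
the summary also reports the count of genes above the threshold, since a
per-gene regulated subset is a separate, looser notion.

**Syntenic translation.** A called haplotype block is translated to the
other species by: block center $= start + (end-start)/2$; nearest source
gene by midpoint distance (walking outward to the nearest gene *with* an
ortholog; equidistant candidates resolve to the smaller start coordinate);
ortholog gene center the same way; window of `window_mb` (default 10 Mb)
centered there, 1-based inclusive, clipped at 1. BED export converts to
0-based half-open coordinates explicitly.

**Isoform-level cis mapping.** Within a window the same sampler runs per
isoform with $\pi$ recomputed for the windowed SNP count. Genotype-group
differences are tested by tie-corrected Kruskal–Wallis at **one shared
lead SNP** — the windowed SNP with the highest MPPI over all isoforms —
with Benjamini–Hochberg FDR across isoforms. Using each isoform's private
best SNP instead would impose a winner's-curse on null isoforms (false
FDR < 0.05 calls in roughly a third of seeds when prototyped); the shared
regulatory SNP matches how the motivating study displayed and tested
isoform effects. Genotype groups with fewer than 2 samples are dropped
with a warning; fewer than 2 remaining groups gives $P = 1$, flagged.

# Regulator profiling

A candidate regulator gene is Spearman-correlated with every module gene
separately per cohort (Student-$t$ $P$, Benjamini–Hochberg FDR across the
module's genes only — the denominator is the module size, not the
genome). Cohort correlation distributions are compared by a two-sided
Mann–Whitney $U$ test with the direction given by the median difference.
The *core set* is the genes with FDR below threshold (default 0.01) in
every cohort, by default also requiring a positive correlation in every
cohort, sorted by mean correlation.

# The synthetic-data generator

The generator emulates the statistical structure the analyses assume, not
the raw data:

- **Genotypes**: binary two-founder strain-distribution patterns in LD
  blocks (all SNPs in a block identical), minor-allele frequency drawn in
  $[0.2, 0.5]$ per block; diploid cohorts use 0/1/2 dosages under
  Hardy–Weinberg. Synthetic coordinates tile blocks every 50 kb, 100
  blocks per chromosome, 1-based.
- **Panel expression**: one latent factor per module per strain,
  $f_m \sim N(0,1)$; the hotspot module's factor gains
  $\mathrm{effect} \times \mathrm{dosage}$; gene $g$ is
  $\lambda_g f_m + \varepsilon$ with $\lambda_g \sim U(0.4, 0.9)$
  (co-expressed but not collinear) and noise SD 0.3 by default;
  background genes are independent $N(0,1)$.
- **Case/control cohorts**: equicorrelated single-factor construction
  $\sqrt{\rho}\,f + \sqrt{1-\rho}\,\varepsilon$, since every downstream
  statistic touches only pairwise correlations; the planted module is
  co-expressed in cases and decorrelated in controls. An optional
  regulator gene loads on the module factor per cohort.
- **Phenotypes**: two fibrosis-like traits
  $= \mathrm{loading} \times$ eigengene
  $+ \mathrm{confounder} \times$ BP-like covariate $+$ noise.

**Hotspot effect default (3 SD) — power analysis.** Calling a locus needs
median BF > 100 across module genes, i.e. per-gene variance explained
$R^2 \gtrsim 0.37$ at $n = 30$ under the $g=n$ slab. A per-allele factor
shift $\delta$ on a binary predictor with allele-frequency variance
$v \le 0.25$ explains at most $\delta^2 v / (1 + \delta^2 v)$ of the
factor — at $\delta = 1.5$ that caps at 0.36, *below* the calling bar
regardless of gene noise, and the realized factor–dosage correlation
additionally fluctuates across panels with SD ≈ 0.07–0.08 (the factor
draw is shared by all module genes). The default $\delta = 3$ targets
expected $R^2 \approx 0.55$, keeping the per-panel failure probability at
the few-percent level. This default is configuration chosen for adequate
recovery power at $n = 30$, not a claim about real effect sizes — though
a median BF near 180 at $n = 29$, as reported for the motivating rat
locus, corresponds to per-gene $R^2 \approx 0.4$, i.e. the same regime.

**What the generator does not emulate**: read counts, library-size and
length effects, isoform structure, batch effects, population structure or
realistic LD decay (blocks are exchangeable), non-Gaussian expression
noise, and correlated background genes. Passing the recovery suites
therefore demonstrates the *statistical machinery* is correct and
calibrated under its assumed model; it does not validate robustness to
everything real tissue data adds.

# Preprocessing conventions

Expression filters keep genes above 1 FPKM in at least
$\max(1, \lceil 0.05\,n \rceil)$ samples (two samples at $n = 30$); zeros
are replaced by the global minimum positive value before $\log_2$.
Covariate adjustment is OLS residualization (categoricals one-hot with a
dropped level; rank-deficient designs are rejected naming the collinear
columns). Sample QC clusters samples by average linkage on Euclidean
distance and cuts at the 0.99 quantile of merge heights, keeping the
largest cluster; note that by construction *something* is always outside
the largest cluster, so the removal list is rarely empty — and on a
genotyped panel with a strong planted hotspot the allele carriers *are*
an expression cluster, which is why the demo applies this QC to the
case/control cohorts (as the motivating study did) and not to the strain
panel. Traits are inverse-normal transformed with offset
$(\mathrm{rank}-0.5)/n$ (average ranks on ties) and then residualized on
the blood-pressure covariate; the fixed 0.5 offset differs negligibly
from the offset-switching convention of `qnorm`-based transforms at
$n \le 10$.

# Problem sizes and runtime

The bundled demonstration and the test/acceptance suites run at desk
scale, chosen so the full suite completes in a few minutes on one core:
panels of 30 strains with 50–100 LD blocks, modules of 20–50 genes among
150–200, cohorts of 40–100 samples, GSEA at 300–1,000 permutations,
dispersion tests at 999 permutations (100,000 where the permutation floor
itself is the quantity of interest), samplers at 2,000 iterations for
recovery runs and 50,000 where compared to exact enumeration. Defaults in
`pipeline_config()` remain at the full-scale values (10,000 GSEA
permutations, 100,000 dispersion permutations, $E(p_g)=2$, BF threshold
100, 10 Mb window, core-set FDR 0.01).

# Known limitations

- Dense matrices throughout; no block-wise decomposition beyond ~20k
  genes.
- No hotspot sharing across responses in the sampler (see above), so
  power at very small effects is lower than a hierarchical sampler could
  achieve.
- The static tree cut does not adapt to nested or overlapping module
  structure.
- Missing values are rejected at load time; no imputation.
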