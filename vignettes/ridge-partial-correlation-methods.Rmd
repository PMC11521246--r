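---
title: "Gene-specific ridge partial correlation: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-specific ridge partial correlation: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(RidgePcor)
```

# The estimand

Marginal co-expression between two genes mixes direct co-regulation with
correlation relayed through third genes. The classical remedy, the partial
correlation given *all* other genes, removes indirect signal but is noisy or
undefined when the number of genes approaches the number of samples, and it
conditions indiscriminately on genes that have no plausible mechanistic link
to the pair.

`RidgePcor` estimates a middle ground. For a gene pair $(i, j)$, each gene is
residualized on a set of *controlling genes* by a generalized ridge
regression whose penalty is specific to each controlling gene:

$$\hat\beta \;=\; \arg\min_\beta \;\|y - Z\beta\|_2^2 \;+\;
  \|\lambda_{i,j} \cdot \beta\|_2^2 ,$$

where $\lambda_{i,j}$ is a penalty vector over the controlling genes and
$\cdot$ is the elementwise product; the coefficients of $i$ and $j$
themselves are constrained to zero (they are simply excluded from $Z$). The
partial correlation reported for the pair is the Pearson correlation of the
two residual vectors,
$\mathrm{PCorr}(g_i, g_j) = \mathrm{Corr}(r_{i,j},\, r_{j,i})$. Both
regressions of a pair use the same controlling set and penalties, so the
resulting matrix is exactly symmetric.

In closed form the coefficients are
$\hat\beta = (Z^\top Z + \mathrm{diag}(\lambda^2))^{-1} Z^\top y$: reading
$\|\lambda \cdot \beta\|_2^2$ literally squares each penalty inside the
norm. This "squared" form is the package default; the classical
generalized-ridge alternative $(Z^\top Z + \mathrm{diag}(\lambda))^{-1}$ is
available via `penalty = "standard"` throughout.

# Prior-guided penalties

The penalty for controlling gene $k$ is the reciprocal of its personalized
PageRank score on a biological prior network (for instance a
protein–protein interaction graph), with restart mass split equally over
the two seeds $i$ and $j$. Genes topologically close to the pair are cheap
to condition on; remote or absent genes are expensive or excluded.

Two implementation facts matter:

* For an undirected graph loaded from an edge list there are no dangling
  nodes, and personalized PageRank is linear in the restart distribution.
  A run restarted uniformly on $\{i, j\}$ therefore equals the average of
  the two single-seed runs. `priorScores()` exploits this: it computes one
  single-seed vector per gene and `regularizationVector()` averages rows,
  so a whole analysis needs $p$ PageRank runs rather than
  $\binom{p}{2}$.
* Genes absent from the prior graph (or unreachable from both seeds) have
  score zero and penalty $\infty$; they can never be selected as
  controlling genes.

`normalizeRegularization()` then keeps the `nGenes` genes with the smallest
penalties (ties broken lexicographically by gene id) and rescales the kept
penalties multiplicatively so their minimum equals `minLambda`. The two
knobs span a family of estimators:

* `nGenes = 0` — no conditioning: the marginal Pearson correlation,
  whatever `minLambda` (the parameter grid collapses these settings into
  one).
* `minLambda = 0` — unpenalized regression on the selected controls; with
  `nGenes` = all other genes this is the canonical partial correlation.
* Large `minLambda` — heavy shrinkage everywhere; the estimate returns
  toward the marginal correlation.

The default grid crosses `nGenes` $\in \{0, 1, 5, 10, 25, 50, 75, 100\}$
with `minLambda` $\in \{0, 0.1, 1, 10\}$, i.e. 29 distinct settings.

When a subset of genes is analysed (`genes =` argument), pairs range over
the subset but controlling genes are still drawn from *every* gene of the
expression matrix. This mirrors the intended use: pairs from a genomic
region of interest, conditioned on transcriptome-wide controls.

All computations standardize gene columns to zero mean and unit variance
first, which makes a single `minLambda` comparable across genes and leaves
the residual correlation unchanged. Internally, one cross-product matrix
$S = X_s^\top X_s$ per data set supplies every pair regression; resampling
procedures therefore recompute $S$ once per resample, not per pair.

# Edge inference

`significantEdges()` bootstraps individuals (default 1000 resamples) and
tests each pair's bootstrap distribution one-sidedly against a pooled
threshold: the 95th percentile of all observed partial correlations for
positive observed values, the 5th for negative. Testing against a pooled
percentile rather than zero retains only edges that are strong relative to
the network-wide distribution.

The default statistic is $t = (\bar{b} - \tau)/s_b$ with $B - 1$ degrees
of freedom, where $\bar b$ and $s_b$ are the bootstrap mean and standard
deviation. The bootstrap spread estimates the sampling standard error of
the partial-correlation *estimate*, so this is the coherent scale on which
to compare the parameter with the threshold: its power is governed by the
data, not by the number of resamples. The classical one-sample mean test
(denominator $s_b/\sqrt{B}$) is available as `method = "tmean"`, but note
that its power grows without bound as $B$ increases — with $B = 1000$
essentially every edge above the pooled 95th percentile becomes
significant, which defeats null calibration.

`differentialEdges()` compares two populations with the statistic
$\Delta = \mathrm{pcor}_A - \mathrm{pcor}_B$ and a label-permutation null
(group sizes preserved). The default test is two-sided on
$z = (\Delta_{obs} - \bar\Delta_{null})/s_{null}$ with `nPerm - 1` degrees
of freedom; `method = "empirical"` gives the add-one permutation p-value.
Benjamini–Hochberg control uses FDR 0.01 for single-population edges and
0.1 for differential edges by default.

`consensusDifferentialEdges()` aggregates differential calls across grid
settings with at least `minNGenes` (default 5) controlling genes,
reporting per edge the number of settings in which it was significant and
its mean $\Delta$.

# Consensus clustering and co-clustering significance

`clusterModularity()` partitions an edge network by greedy modularity
maximization (Clauset–Newman–Moore, via igraph), where modularity is

$$Q = \sum_c \left[\frac{L_c}{m} - \left(\frac{k_c}{2m}\right)^2\right].$$

`modularityScore()` evaluates this sum directly (it is also cross-checked
against igraph and a brute-force all-partitions oracle in the test suite).
Running the clustering across grid settings gives one partition per
setting; `coOccurrence()` counts, per gene pair, in how many partitions
the two genes share a module, and `consensusClusters()` cuts an
average-linkage dendrogram of the dissimilarity $1 - C/R$ into `k`
clusters (default 10).

`coClusterSignificance()` asks whether a pair co-clusters more often than
chance: under random assignment the expected number of co-clusterings is
$\lambda = \sum_r \sum_c (n_{r,c}/N)^2$ (each partition contributes its
squared cluster-size proportions), and the observed count is tested
against $\mathrm{Poisson}(\lambda)$ upper tails with BH control at FDR
0.05.

# GWAS locus clustering

`countRegions()` counts windows of `k` consecutive same-chromosome loci
(after sorting) whose span is at most `regionLength`; overlapping windows
each count. `clusteringPvalue()` compares the observed count with its
Monte-Carlo null under uniform placement: a chromosome is drawn with
probability proportional to its length (the bundled layout is the hg38
autosomes plus X) and the position uniformly within it. The p-value uses
the add-one convention $(1 + \#\{\text{sims} \ge \text{obs}\})/(n + 1)$,
which never returns zero.

# Synthetic ground truth

`makePrecision()` builds a Gaussian graphical model with precision matrix
$\Omega = I - s\,A$ over a chosen edge set $A$: the implied partial
correlation is exactly $s$ on every edge and $0$ elsewhere, with no
approximation. The model is positive definite iff
$s < 1/\lambda_{\max}(A)$; infeasible strengths raise an error reporting
that bound. This cleanly separates "how strong is a direct link" from
"which links exist", at the price of coupling the feasible strength to the
graph's spectral radius — dense graphs only admit weak direct links,
which is the mathematically unavoidable trade-off for exact planted
values. `sampleCohort()` draws multivariate-normal cohorts from
$\Omega^{-1}$, `makeDifferentialPair()` labels two cohorts and records
pairs whose implied values differ by more than a margin, and `makePrior()`
degrades the true structure into a partially concordant prior graph
(a fraction of true edges kept, plus spurious ones).

# Behaviour of the grid medians, and a negative result

The distribution of $|\mathrm{pcor}|$ across all pairs contracts as
`nGenes` grows: each added control removes more relayed signal, so the
median falls from the marginal level toward a conditional noise floor.
This holds robustly in simulation; in a strongly co-expressed module
(near-critical model, median marginal $|r| \approx 0.5$) the decline is
steep and monotone.

The companion intuition — that the median should *rise* with `minLambda`,
because heavier shrinkage conditions "less" — holds only in part on data
with known ground truth, and the package's simulations make the mechanism
explicit:

* With few controlling genes (1–10), the selected controls are
  prior-proximal mediators whose Gram-matrix scale is comparable to the
  penalty, so `minLambda = 10` visibly retains mediated signal: those grid
  cells sit consistently above their unpenalized counterparts.
* With many controlling genes, the grid median is dominated by pairs whose
  conditional dependence is (near) zero. For such pairs ridge shrinkage
  *reduces* the estimate: the residual noise scale moves from roughly
  $1/\sqrt{n - m}$ (unpenalized, $m$ controls) toward $1/\sqrt{n}$
  (fully shrunk), a genuine decrease. The countervailing rise — penalties
  strong enough to stop the controls from absorbing shared signal, pushing
  residual correlations back toward the marginal level — requires
  $\lambda^2$ on the order of the leading eigenvalues of the control Gram
  matrix ($\approx n \times$ shared-factor variance, i.e. $\lambda$ in the
  hundreds for $n = 500$), far beyond the default grid's maximum of 10.

So over the default grid the median's response to `minLambda` is a shallow
dip before an eventual (off-grid) rise: as a monotone trend claim it fails
on Gaussian graphical model data, and the acceptance test that asserts it
(Spearman trend of grid medians) is expected to stay red on that half.
This is a structural property of the estimator under a null-dominated
median, not a tuning issue; on real co-expression data, where typical
pairs carry mediated signal at many scales, a directional increase can
still be observed.

The shrinkage-trend simulation uses a 100-gene Erdős–Rényi model with 400
edges, edge strength $0.995/\lambda_{\max}(A)$ (just inside positive
definiteness, giving the strong module-wide co-expression typical of a
disease-risk region), $n = 500$ samples, and a prior that keeps 50% of
true edges plus 200 spurious ones — informative but imperfect, like a
real interactome.

# Other fixed numerical choices

* PageRank damping 0.85 (the standard choice); scores from igraph's
  algebraic solver (PRPACK), accurate well below $10^{-10}$.
* Standardization uses the $n - 1$ variance convention; zero-variance
  genes are flagged and their pairs reported as 0 with `flagged = TRUE`.
* Singular ridge systems (possible at `minLambda = 0` with collinear
  controls) fall back to the Moore–Penrose pseudo-inverse.
* Partial correlations are clamped to $[-1, 1]$ against floating-point
  overshoot; residual variances below $10^{-12}$ are treated as
  degenerate.
* Edge tables are written with 6 significant digits; partial-correlation
  and expression matrices at full precision.

# A small worked example

```{r example, eval = FALSE}
model <- makePrecision(30, density = 0.1, strength = 0.25, seed = 1)
x <- sampleCohort(model, 400, seed = 2)
prior <- priorScores(makePrior(model, concordance = 0.8, extraEdges = 20,
                               seed = 3), model@genes)
res <- pcorMatrix(x, prior = prior, nGenes = 10, minLambda = 0.1)
edges <- significantEdges(x, prior, nGenes = 10, minLambda = 0.1,
                          nBoot = 200, seed = 4)
net <- geneNetwork(edges, model@genes)
clusterModularity(net)$Q
```

The chunk is not evaluated during vignette builds to keep installation
fast; the README shows the same workflow with its actual printed output.
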