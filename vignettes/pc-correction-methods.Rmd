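---
title: "Principal-component confounder correction for co-expression networks: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Principal-component confounder correction for co-expression networks: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Gene co-expression networks are reconstructed from an expression matrix
$E$ (genes $\times$ samples) on the premise that correlated genes are
functionally related. Technical and unwanted biological artifacts — batch,
RNA integrity, mapping bias, GC content — perturb many genes at once and so
induce *broad* correlation that standard network learners (sparse inverse
covariance estimation, weighted co-expression modules) happily convert into
edges. The result is dense networks full of false discoveries.

pcnet implements a correction built on one structural assumption: the true
network is **sparse and scale-free**. Under that assumption network signal
is concentrated in small groups of genes (hubs aside, most genes have few
neighbours), so no single network component is broad enough to dominate the
leading principal components of the expression matrix. The top components
instead capture the confounders, and regressing them out of every gene
removes the artifact signal while leaving the sparse network structure
largely intact. When the true network contains large, densely connected
subgraphs — or when a strong biological contrast such as tumour versus
normal drives broad expression differences — the assumption fails and the
correction can remove signal of interest; the method should be used with
that caveat in mind.

# The correction model

Let $Z$ be the gene-wise standardized matrix (each gene centred and scaled
to unit variance) and let $L_{1:p}$ be the first $p$ right-singular vectors
of $Z$ — the component scores over samples. For each gene $i$ the package
fits, by ordinary least squares,

$$ E_i = \mu_i + \beta_i L_{1:p} + \varepsilon_i $$

and replaces the gene with its residual

$$ \widehat{E}_i = E_i - \big[\mu_i + \beta_i L_{1:p}\big]. $$

Two conventions deserve emphasis:

* **Components are extracted from the standardized matrix, but the
  regression runs on the original scale.** Standardizing first stops
  high-variance genes from dominating the components; residualizing the
  original matrix preserves each gene's scale for downstream tools. The
  `residualizeStandardized` flag switches the regression target to $Z$
  for pipelines that want fully standardized residuals.
* **"Loadings" live in sample space.** Because the $L$ vectors are used as
  sample-indexed regressors in a per-gene regression, they must be the
  right-singular (sample-side) vectors. The word "loading" is ambiguous in
  the PCA literature, so `componentScores()` names them what they are.

Since the scores are orthonormal, centred, and orthogonal to the
intercept, the fit reduces to a projection: residuals are *exactly*
mean-centred and orthogonal to every removed score (machine precision;
`pcResidualize()` is tested to $|r| < 10^{-8}$). With $p = 0$ the
operation is per-gene mean-centring. Singular-vector signs are fixed by
forcing each score's largest-magnitude entry positive, so stored
coefficients are deterministic; residuals are invariant to sign and to
rotations within ties of equal singular values (the latter only up to
numerical noise, which is why coefficients — not residuals — carry the
determinism guarantee).

# Choosing the number of components

`estimateNumPC()` uses permutation-based parallel analysis. Observed
per-component variance proportions $d_i^2 / \sum_k d_k^2$ are compared
with those of matrices in which every gene row is independently permuted
across samples — destroying gene–gene correlation while keeping every
gene's marginal distribution. Component $i$ is significant when its
permutation p-value

$$ p_i = \frac{1 + \#\{b : d^{(b)2}_i/\textstyle\sum_k d^{(b)2}_k \ge d_i^2/\sum_k d_k^2\}}{B + 1} $$

is at most $\alpha$, after enforcing monotone non-decreasing p-values
across components; the returned $p$ is the longest significant prefix.
This is the standard finite-$B$ permutation convention and is equivalent
to comparing the observed proportion against the
$\lceil (1-\alpha)(B+1) \rceil$-th order statistic of the permuted ones.

Defaults are $B = 20$ permutations and $\alpha = 0.10$, both exposed.
Replicate $b$ derives its seed as `seed + b`, so runs are reproducible and
individual replicates are independently reproducible.

Calibration is inherently bounded by $\alpha$: on pure noise the observed
and permuted proportions are exchangeable, so the probability of returning
$0$ is about $1 - \alpha$ (empirically $\approx 0.92$ at the defaults with
the conservative $(b+1)/(B+1)$ rule) — no permutation test at
$\alpha = 0.10$ can push this above $0.95$. Power is excellent: planted
orthogonal factors at signal-to-noise $\ge 5$ are recovered within $\pm 1$
essentially always in the tested regimes ($k \in \{1, 3, 5\}$, 200 genes
$\times$ 80 samples).

Two behaviours worth knowing:

* On data that genuinely contain a correlated network but no confounders,
  the estimator does **not** return 0 — real correlation also beats the
  permuted null. On clean simulated scale-free data it typically returns
  a few dozen components, which mirrors what the same scheme reports on
  real tissue data. The method's claim is not that $p$ counts confounders;
  it is that for scale-free networks the *top* components are dominated by
  artifacts whenever artifacts are present.
* With several confounders of comparable strength, individual components
  mix them (rotational ambiguity); the removed *subspace* still captures
  them, which is what matters for residualization.

## Covariate baselines

`covariateResidualize()` implements the comparison arms: per-gene OLS on
measured covariates (RIN, exonic rate, GC bias, or any subset) jointly.
`selectCovariates()` reproduces the "explains at least 1% of expression
variance" screen: each covariate is fit singly per gene, per-gene
*adjusted* $R^2$ values are averaged across genes (mean by default; median
available), and covariates with aggregate $\ge 0.01$ are kept. Because
adjusted $R^2$ is negative in expectation's neighbourhood under the null,
the aggregate is approximately zero-centred for an irrelevant covariate —
which is exactly what makes the 1% threshold meaningful, but also means a
threshold of 0 does not trivially keep everything.

# The simulator

`simulateScaleFree()` generates the benchmark's study conditions:

1. **Graph**: Barabási–Albert preferential attachment
   (`igraph::sample_pa`, `attachmentEdges` new edges per node, default 1).
   The degree distribution is power-law-like (maximum-likelihood exponent
   of generated instances falls in $[2, 3.5]$); the graph is connected by
   construction.
2. **Precision matrix**: off-diagonal entries drawn uniformly in magnitude
   from `edgeWeightRange` (default $[0.3, 1]$) with random sign, exactly
   on the graph's support; the diagonal is set to the row-wise sum of
   absolute off-diagonal entries plus $\delta = 0.1$. Strict diagonal
   dominance guarantees positive definiteness without disturbing the
   support, so the true conditional-independence graph equals the
   generated one by construction.
3. **Expression**: iid multivariate Gaussian draws with that precision,
   via the Cholesky factor. Location and scale are irrelevant downstream
   (the pipeline standardizes per gene), so the signal is zero-mean.
4. **Confounders**: for each of $k$ confounders, per-sample values
   $\sim N(0, \sigma_c^2)$ and a uniformly random affected gene subset of
   size `round(affectedFraction * nGenes)` with loadings $\sim N(0,1)$
   (zero elsewhere); the confounded matrix is
   $E + \Lambda C^\top$. Affected subsets are drawn independently per
   confounder and may overlap, as batch-like artifacts do.

Benchmark defaults — **300 genes, 200 samples, 5 confounders, 30% of
genes affected, confounder sd 3** — are the conditions under which the
package's comparative claims are evaluated; the simulator scales to other
sizes but these are the sizes the shipped experiments use (chosen so the
full 20-seed comparison completes comfortably on a laptop core).
`toyExample()` fixes a 20-gene, 50-sample, single-confounder instance for
documentation and fast tests.

What the simulator does *not* emulate: count noise (data are Gaussian, not
negative binomial), mean–variance relationships, outlying samples,
non-linear confounder effects, and correlated confounders. Passing the
shipped benchmarks therefore demonstrates correctness of the method under
its own model assumptions, not performance on any particular real dataset.

# Network reconstruction

## Graphical lasso

`glassoPrecision()` maximizes
$\log\det\Theta - \mathrm{tr}(S\Theta) - \lambda \sum_{i \ne j} |\Theta_{ij}|$
by block coordinate descent (row-wise lasso subproblems solved by
soft-thresholded coordinate descent), with these conventions, each of
which affects edge counts at a given $\lambda$ and is therefore stated
explicitly:

* the penalty applies to **off-diagonal entries only**;
* the input is the **sample correlation matrix**, so $\lambda$ is
  scale-free and the solution is exactly diagonal once
  $\lambda \ge \max_{i \ne j} |S_{ij}|$;
* an edge is called when $|\Theta_{ij}|$ exceeds `edgeTolerance`
  ($10^{-8}$ by default) — coordinate descent produces exact zeros, so the
  threshold only guards against numerical dust after symmetrization;
* convergence is declared when the mean absolute update of the working
  covariance falls below `convergenceTol` (default $10^{-4}$) times the
  mean absolute off-diagonal of $S$; non-convergence is an error naming
  the penalty and iteration count, never a silent result.

`glassoPath()` solves a decreasing penalty sequence with warm starts;
per-penalty solutions match cold starts to solver tolerance. The default
demonstration path is $\lambda = 0.8, 0.7, \ldots, 0.3$: above 0.8 even
confounded data are near-empty, below 0.3 the 300-gene solve becomes dense
and slow with no extra insight. On three-variable instances the solver is
tested against brute-force numerical minimization of the same objective
(cyclic one-dimensional optimization), agreeing elementwise to $10^{-3}$.

## Signed modules

The module route is the conventional one: signed adjacency
$a_{ij} = ((1 + r_{ij})/2)^\beta$ (Pearson $r$, default $\beta = 6$),
unsigned topological overlap

$$ \mathrm{TOM}_{ij} = \frac{\sum_{u \ne i,j} a_{iu}a_{uj} + a_{ij}}
   {\min(k_i, k_j) + 1 - a_{ij}}, $$

average-linkage clustering of $1 - \mathrm{TOM}$, and a **static** cut at
each requested height: clusters of at least `minModuleSize` (default 30)
genes become modules, everything else is the grey/unassigned module, and
modules are interpreted as cliques when converted to edge sets. A static
cut family — not dynamic hybrid cutting — is what a cut-height sweep
traverses; dynamic cutting is deliberately out of scope. `hclust`'s
deterministic merge ordering breaks ties, and one clustering serves all
cut heights, so path points are mutually consistent and nested (edge
counts are non-decreasing in cut height).

# Evaluation conventions

Ground truth is a set of unordered gene pairs: either pathway
co-membership (any two genes sharing $\ge 1$ pathway, from GMT files, with
one database label per file so pairs can be restricted to those supported
by $\ge 2$ databases) or the simulator's true adjacency. Counts follow the
edge-level definitions: TP = inferred $\cap$ truth, FP = inferred
$\setminus$ truth, FN = truth $\setminus$ inferred, with truth restricted
to the network's gene universe *before* any counting;
$\mathrm{FDR} = \mathrm{FP}/(\mathrm{TP}+\mathrm{FP})$ and
$\mathrm{FNR} = \mathrm{FN}/(\mathrm{TP}+\mathrm{FN})$.

Degenerate denominators return `NaN`, and such points are excluded from
summary curves: silently reporting 0 would award perfect FDR to an empty
network. Local clustering coefficients are averaged over nodes of degree
$\ge 2$ only. "Hub" has no canonical definition, so the default is the
top-5% degree quantile with an absolute override, and the threshold used
is always echoed in the report's parameters.

# Reproducibility

Every stochastic stage takes an integer seed; composite stages derive
sub-seeds by fixed offsets from one master seed (simulation stages use
offsets 1–4; the pipeline's correction uses offset 101), so any stage can
be reproduced in isolation and identical configurations produce identical
outputs. `runPipeline()` writes a JSON config echo carrying the package
version, an MD5 hash of the canonical serialisation of the complete
configuration, and the seed; the hash changes if any parameter (including
the seed) changes and is invariant to field order.

# Known limitations

* The correction assumes broad components are artifacts. Dense true
  subnetworks, strong sample stratification of biological origin, or
  designs with a primary variable of interest violate this; the package
  deliberately does not implement the protected (model-matrix) variant of
  surrogate variable analysis.
* Parallel analysis counts *significant* components, not confounders; on
  confounder-free but genuinely correlated data it returns a positive
  count and some signal is removed (false negative rates are not improved
  by the correction — only false discoveries are).
* The graphical lasso solver targets the moderate dimensions of the
  shipped experiments (hundreds of genes); for thousands of genes at
  small penalties a specialised solver would be preferable.
* Gene identifiers are matched by exact, case-sensitive string equality
  throughout; no alias resolution is attempted, because silent aliasing
  would make results irreproducible.
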