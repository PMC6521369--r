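# pcnet

Principal-component confounder correction for gene co-expression network
reconstruction — with the simulation and evaluation machinery to show that
it works.

## The problem

Latent artifacts in expression data (batch, RNA integrity, exonic mapping
rate, GC bias, unmodelled biology) perturb many genes at once. Network
learners read the resulting broad correlation as co-expression, so
networks reconstructed from uncorrected data are dense and full of false
edges. For **sparse, scale-free** networks, however, true network signal
is too localized to dominate the leading principal components of the
expression matrix — the top components capture the artifacts instead.
Regressing them out of every gene before reconstruction removes the
confounding while leaving sparse network structure intact.

Given a standardized expression matrix with component scores
`L_(1:p)` (right-singular vectors), each gene `E_i` is corrected by OLS:

    E_i      = mu_i + beta_i * L_(1:p) + eps_i
    E_i_hat  = E_i - [mu_i + beta_i * L_(1:p)]

with `p` chosen by permutation parallel analysis: a component is kept when
its observed variance-explained proportion beats the permuted null
(per-gene row permutations, `B = 20`, `alpha = 0.10`) at the
`(1+b)/(B+1) <= alpha` rule, and `p` is the longest significant prefix.

The package provides:

* `correctExpression()` / `estimateNumPC()` / `pcResidualize()` — the
  correction itself, plus `covariateResidualize()` and
  `selectCovariates()` for measured-covariate baselines (RIN & friends);
* `glassoNetwork()` / `glassoPath()` — L1-penalised sparse inverse
  covariance estimation (off-diagonal penalty, correlation input,
  warm-started penalty paths; coordinate-descent core in C++);
* `signedAdjacency()`, `tomSimilarity()`, `detectModules()`,
  `wgcnaPath()` — signed weighted co-expression modules over a static
  cut-height path, modules interpreted as cliques;
* `simulateScaleFree()` / `toyExample()` — scale-free Gaussian graphical
  model simulator with injected low-rank confounders and full ground
  truth;
* `pathwayPairs()`, `confusionCounts()`, `edgeFDR()`, `edgeFNR()`,
  `evaluateNetwork()`, `clusteringStats()`, `moduleSizeStats()` —
  edge-level scoring against pathway (GMT) or simulated truth, plus
  topology diagnostics;
* `runPipeline()` — the end-to-end benchmark (simulate → correct →
  reconstruct → evaluate) and a thin CLI at `inst/scripts/pcnet.R`.

## Worked example

```r
library(pcnet)

res <- runPipeline(seed = 3)   # 300 genes x 200 samples, 5 confounders
res$p
#> [1] 5
res$summary
#>   method          arm median_fdr median_fnr total_edges
#> 1 glasso pc_corrected 0.03141361  0.5183946         962
#> 2 glasso  uncorrected 0.98665704  0.8829431       16018
```

The simulator plants a scale-free network (300 genes, 200 samples) and
injects 5 latent confounders, each shifting 30% of genes with per-sample
sd 3. The permutation scheme estimates `p = 5` — exactly the planted
confounders — and after removing those 5 components the graphical lasso
recovers the network with a median FDR of 0.03 across the penalty path,
versus 0.99 from the uncorrected matrix, using 16x fewer edges. Per-path
detail sits in `res$results` (one row per arm and penalty):

```r
head(subset(res$results, arm == "pc_corrected",
            c(param, tp, fp, fn, fdr, n_edges)))
#>    param  tp fp  fn         fdr n_edges
#> 7    0.8   0  0 299         NaN       0
#> 8    0.7  36  0 263 0.000000000      36
#> 9    0.6 103  1 196 0.009615385     104
#> 10   0.5 185  6 114 0.031413613     191
#> 11   0.4 221 37  78 0.143410853     258
#> 12   0.3 264 109  35 0.292225201     373
```

(The `NaN` is deliberate: an empty network has undefined FDR and is
excluded from summaries rather than scored as perfect.)

For real data the same pieces compose manually: `readExpression()` →
`selectMostVariable(expr, 5000)` → `correctExpression()` →
`glassoPath()`/`wgcnaPath()` → `pathwayPairs(readGMT(...), universe)` →
`evaluateNetwork()`.

## Design notes

The methods vignette (`vignettes/pc-correction-methods.Rmd`) documents the
model, the permutation scheme and its calibration ceiling, every solver
convention that affects edge counts, what the simulator does and does not
emulate, and known limitations.
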