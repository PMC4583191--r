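# ruvclean

Removal of unwanted variation for gene co-expression analysis.

## The problem

Gene co-expression — dependence between two genes' expression profiles,
usually measured by the Pearson correlation coefficient (PCC) — underpins
network construction, gene annotation, and guilt-by-association disease-gene
prioritization. The PCC assumes independent samples, and large expression
studies violate that assumption as a matter of course: batches, sites,
platforms and other systematic noise induce sample dependence. When that
noise dominates, close to half of all estimated correlation signs are wrong,
and standard normalizations (quantile normalization, background correction)
do not help, because they only adjust marginal distributions and offsets
while the noise is multivariate.

`ruvclean` is for analysts who want to estimate gene–gene correlations from
noisy high-dimensional expression data. It implements the unsupervised
RUV-random strategy, specialised to correlation estimation: under the model

    Y = X beta + W alpha + eps,        Y in R^(m x n), log-2 scale,

negative-control genes c (no biological signal: `beta_c = 0`) reveal the
noise structure `Y_c = W alpha_c + eps_c`. The cleaning is four steps:
center each gene (`Y* = (I - J/m) Y`); estimate `W_hat = U_k D_k` by SVD
factor analysis of the centered controls; ridge-regress all genes on the
factors, `alpha_hat = (W'W + nu I)^(-1) W'Y*`; subtract `W_hat alpha_hat`.
Accuracy against a known truth is scored by the squared average error on the
Fisher z scale, `FN^2 = 2 sum_{i<j} (arctanh r_hat - arctanh r)^2 / (n(n-1))`,
and by the percentage of truly correlated pairs estimated with the wrong
sign (%WS).

The package also ships the supporting toolkit: a seeded simulation framework
with known correlation structure, comparator normalizations, plot-ready
diagnostics (correlation densities, p-value histograms, modified RLE
summaries, PCA projections), negative-control discovery, and
guilt-by-association candidate prioritization with an honest
"no usable threshold" failure mode.

## Worked example

```r
library(ruvclean)

sim <- simulate_coexpression(simulation_design(seed = 1))  # 180 x 500, noisy
fit <- ruv_random(sim$Y, sim$controls, k = 3)
fit
#> RUV-random fit for correlation analysis
#>   samples: 180, genes: 500, negative controls: 250
#>   k = 3, nu = 1428.5
#>   proportion of centered variance removed: 0.930

truth <- true_correlations(sim$truth)
metric_report(pearson_matrix(sim$Y, source_label = "raw"), truth)
#> Correlation accuracy [raw]: FN2 = 0.5025, %WS = 46.43 (124750 pairs, 3000 with r != 0)
metric_report(pearson_matrix(residuals(fit), source_label = "RUV-random"), truth)
#> Correlation accuracy [RUV-random]: FN2 = 0.006473, %WS = 0.33 (124750 pairs, 3000 with r != 0)
```

On raw data the systematic noise (93% of the centered variance here) flips
46% of the truly correlated pairs' signs and inflates the Fisher-z error to
0.50; after estimating three noise factors from the 250 negative controls
and removing them, 0.33% of signs are wrong and the error drops two orders
of magnitude. `residuals(fit)` is the cleaned matrix, `coef(fit)` the factor
loadings, `plot(fit)` the scree diagnostic for choosing `k`, and
`suggest_nu_grid(fit)` a ridge-penalty grid to evaluate with the
diagnostics.

A file-based pipeline (`run_config()` / `run_pipeline()`) and a thin CLI
(`inst/cli/ruvclean.R` with `simulate` / `normalize` / `clean` / `evaluate`
/ `diagnose` / `prioritize` / `run` subcommands) wrap the same functions for
reproducible runs with manifests.

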