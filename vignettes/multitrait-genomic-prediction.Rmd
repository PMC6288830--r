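---
title: "Multi-trait multi-environment genomic prediction: models and methods"
author: "mtmegp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-trait multi-environment genomic prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtmegp)
```

## The problem

Breeding programs phenotype a panel of $J$ genotyped lines for $L$
correlated traits across $I$ environments, and need to predict the cells
of the line-by-environment grid that were never grown — a breeder wants
to know how an untested line-environment combination would have
performed, using that line's records in *other* environments and the
genomic relationships among lines. `mtmegp` implements and compares two
engines for this task, together with the marker quality control,
cell-level cross-validation and accuracy metrics around them, and a
simulator that generates data from the mixed model's own generative
process so the entire pipeline is testable without field data.

## The Bayesian mixed model

With $n = J \times I$ cells ordered environment-major and $L$ trait
columns, the model is

$$Y = X\beta + Z_1 b_1 + Z_2 b_2 + E,$$

where $X$ ($n \times I$), $Z_1$ ($n \times J$) and $Z_2$
($n \times IJ$) are incidence matrices, $\beta$ ($I \times L$) holds the
environment-by-trait means, and the random matrices follow matrix-variate
normal distributions (for a matrix $M$, $M \sim \mathrm{MN}(H, \Omega,
\Sigma)$ means $\mathrm{vec}(M) \sim N(\mathrm{vec}(H), \Sigma \otimes
\Omega)$):

* $b_1 \sim \mathrm{MN}(0,\, G_g,\, \Sigma_t)$ — genotype-by-trait
  effects, with $G_g = WW^\top/p$ the genomic relationship matrix of the
  $J$ lines and $\Sigma_t$ the unstructured $L \times L$ genetic trait
  covariance;
* $b_2 \sim \mathrm{MN}(0,\, \Sigma_E \otimes G_g,\, \Sigma_t)$ —
  optional genotype-by-environment-by-trait effects, with $\Sigma_E$ an
  unstructured $I \times I$ environment covariance;
* $E \sim \mathrm{MN}(0,\, I_n,\, R_e)$ — residuals with unstructured
  trait covariance $R_e$.

Without the interaction term, $b_2$ and $\Sigma_E$ are simply not part of
the model. This is the multi-trait, multi-environment generalisation of
GBLUP: a linear model on the genomic-relationship feature space.

### Gibbs sampler and full conditionals

The sampler cycles exact draws of $\beta$, $b_1$, $b_2$, $\Sigma_t$,
$\Sigma_E$ and $R_e$ from their full conditionals, which follow from
multivariate-normal and inverse-Wishart conjugacy:

* $\mathrm{vec}(\beta)$: normal with precision
  $R_e^{-1} \otimes X^\top X + \lambda I$ ($\lambda$ = ridge precision, 0
  for the flat default);
* $\mathrm{vec}(b_1)$: normal with precision
  $\Sigma_t^{-1} \otimes G_g^{-1} + R_e^{-1} \otimes Z_1^\top Z_1$;
* $\mathrm{vec}(b_2)$: normal with precision
  $\Sigma_t^{-1} \otimes \Sigma_E^{-1} \otimes G_g^{-1} +
   R_e^{-1} \otimes Z_2^\top Z_2$;
* $\Sigma_t$: $\mathrm{IW}(\nu_t + J + IJ,\;
  S_t + b_1^\top G_g^{-1} b_1 +
  b_2^\top(\Sigma_E^{-1} \otimes G_g^{-1})b_2)$ (the $b_2$ pieces only
  when the interaction is fitted);
* $\Sigma_E$: $\mathrm{IW}(\nu_E + JL,\; S_E + Q)$ with
  $Q_{ii'} = \mathrm{tr}(\Sigma_t^{-1} b_{2(i')}^\top G_g^{-1}
  b_{2(i)})$ over the per-environment row blocks of $b_2$;
* $R_e$: $\mathrm{IW}(\nu_e + n_{\mathrm{obs}},\; S_e + E^\top E)$ over
  the observed rows.

Because these derivations are the scientific core of the package, their
correctness is certified by tests rather than asserted: brute-force
conditional-mean oracles, moment checks against closed-form
inverse-Wishart means, a 50,000-draw Kolmogorov–Smirnov comparison with
an independent Metropolis sampler targeting the same conditional, and a
joint-distribution ("getting it right") check — `geweke_check()` — that
compares prior-predictive simulation against Gibbs-with-data-resimulation
across 20 test statistics.

### Priors

Defaults are weakly informative and proper: $\mathrm{IW}(\mathrm{dim} +
2, I)$ for each covariance matrix (prior mean the identity) and a flat
prior on $\beta$. All are overridable through `bmtme_priors()`. The
joint-distribution check uses $\mathrm{IW}(\mathrm{dim} + 6, I)$ and a
unit-normal $\beta$ prior instead, because that diagnostic requires
proper priors with finite second moments to make its z-statistics
well-defined.

### Numerical choices

* **Missing cells.** Cross-validation removes whole cells (all $L$
  traits of one line in one environment), so rows of $Y$ with missing
  values are dropped from every likelihood contribution by row-subsetting
  $X$, $Z_1$, $Z_2$. A cell with any missing trait counts as missing.
* **Fast path.** When every line has the same number of observed cells,
  the $b_1$ (and, with all cells observed, $b_2$) conditional decouples
  in the eigenbasis of $G_g$; a simultaneous diagonalisation of
  $(\Sigma_t^{-1}, R_e^{-1})$ then lets all $J$ (or $IJ$) rows be drawn
  with a handful of dense matrix products. Under cross-validation
  masking, replication is unbalanced and the sampler falls back to a
  dense Cholesky draw of the full vectorised conditional. Both paths
  target the same distribution; the test suite checks their conditional
  means agree to $10^{-8}$.
* **GRM conditioning.** $G_g = WW^\top/p$ is used exactly as defined —
  marker codes are *not* centred by allele frequency, and no centring is
  applied silently. A numerically singular or slightly indefinite GRM
  (e.g. from few markers, duplicated lines, or a user-supplied matrix)
  receives a diagonal jitter of $10^{-8}\,\mathrm{tr}(G_g)/J$ so the
  Cholesky and eigendecompositions exist; clearly indefinite matrices
  are rejected.
* **Chain defaults.** `n_iter = 10000`, `burn_in = 5000`, `thin = 2`.
  Convergence is the user's responsibility; the fit reports a
  split-chain potential-scale-reduction factor per scalar parameter as a
  first-line diagnostic. The comparison driver uses shorter chains
  (2000/1000) because cross-validated prediction only needs the
  posterior mean of the linear predictor, which stabilises much earlier
  than the covariance posteriors.
* **Predictions** are posterior means of $X\beta + Z_1 b_1 (+ Z_2 b_2)$
  at the requested cells; unobserved cells are predictable because
  $G_g$ propagates information into their line effects. How the original
  analysis formed test-cell predictions is not stated in print;
  posterior-mean prediction is this package's documented choice.

## The multi-trait deep-learning engine

The second engine is a densely connected feedforward network: an input
layer, `n_layers` hidden layers of `units` ReLU units each, dropout
(rate 0.3 by default) after every hidden layer during training, and one
linear output head with $L$ units — the standard dense multi-task head.
The network is small (at most a few hundred inputs and 100 hidden units
here), so the package implements the forward/backward passes directly in
R matrix algebra with mini-batch Adam (learning rate 0.001, batch size
$\min(32, n)$) on the mean squared error of the standardised responses.
Loss and optimizer are documented package choices — they are not
prescribed by the modelling problem.

### Input encoding

How to present genomes to a network is a genuine design decision. The
package encodes each cell as:

* $I$ one-hot environment indicators;
* $J$ genomic columns: row $j$ of a square-root factor $L_g$ of the GRM
  ($L_g L_g^\top = G_g$; symmetric eigen-root by default, Cholesky
  optional). A *linear* network on this block is exactly GBLUP, which
  makes the encoding interpretable and gives the network the same
  information the mixed model receives;
* optionally all $I \times J$ products of environment indicators with
  genomic columns — the explicit genotype-by-environment block.

### Hyperparameter search

The default grid is the full factorial over units and epochs in
$\{50, 60, 70, 80, 90, 100\}$ and 1–3 hidden layers: $6 \times 6 \times
3 = 108$ configurations. Selection uses a single 80/20 inner split of
the training rows: every configuration is trained on the inner-training
part, scored by validation MSE, and ties are broken toward fewer layers,
then fewer units, then fewer epochs. The winning configuration is
refitted on the full training set before predicting the held-out cells
(refit-on-full-training is the documented default). `epochs` counts full
passes in both phases; there is no early stopping, because the epoch
count is itself a tuned hyperparameter. One user seed drives
initialisation, batch shuffling, dropout masks and the inner split.

## Cross-validation and accuracy

`cv2_partition()` implements the cell-level scheme: with $N$ observed
cells, $m = \mathrm{round}(0.2\,N)$ lines are drawn (with replacement
when $J < m$, without otherwise; round = half away from zero, a
documented choice since the sizing rule does not specify one), one
environment is picked uniformly per drawn line, and the distinct cells
so selected become the test set. Duplicate draws collapse — the test set
is a set. Partitions are independent, so a cell may be tested in several
partitions but never appears in both sides of one.

Accuracy is the Pearson correlation between predicted and observed
values per trait-environment stratum per partition; the mean across
partitions is the reported performance, with the standard error of that
mean (SD across partitions divided by $\sqrt{\text{partitions}}$, a
documented convention). Because strata differ in heritability,
`adjust_by_heritability()` rescales $r / \sqrt{h^2}$; adjusted values
may exceed 1 when $h^2$ is small. Heritabilities are *inputs* — the
package does not estimate them. Whether correlations should instead be
pooled across partitions before averaging is ambiguous in general; this
package averages per-partition correlations and says so.

Responses are standardised per training set (subtract mean, divide by
the $n-1$ sample SD — the denominator is a documented convention) and
predictions are back-transformed, for both engines; this matters more
for the network than for the mixed model, but is applied uniformly.

## The simulator

`simulate_dataset()` draws data exactly from the generative process
above: markers under Hardy–Weinberg proportions with per-marker minor
allele frequencies uniform on [0.05, 0.5], $G_g = WW^\top/p$, then
$b_1$, $b_2$, $E$ from their matrix-variate distributions. Defaults
describe a mid-size trial with moderately heritable, correlated traits:
unit genetic variances with trait and environment correlations 0.5,
residual covariance $0.9 I + 0.1$, and $\beta$ a matrix of distinct
integers so fixed-effect recovery is visually checkable. The realized
per-stratum signal fraction (variance of the genetic value over variance
of the phenotype) is reported as the simulation's heritability, giving
calibrated inputs for the adjusted-accuracy metric.

What the simulator deliberately does *not* emulate: linkage
disequilibrium (loci are independent), population structure beyond what
random allele frequencies induce, selection, pedigree, trait
architectures other than the additive matrix-normal model, and
non-Gaussian residuals. Passing tests therefore certify the machinery —
the samplers, the network, the partition scheme, the metrics — under the
model's own assumptions; they do not certify that real trials satisfy
those assumptions.

## Study scales used by the test suite

The package's own validation runs at sizes chosen to finish on one CPU
core in minutes while still being statistically informative, and the
same sizes are used by `scripts/acceptance.R`:

* matrix-normal density vs the explicit Kronecker construction: 100
  random instances with $np \le 60$, agreement to $10^{-10}$;
* joint-distribution check: $J = 5$, $I = 2$, $L = 2$, 50,000 sweeps of
  each sampler, all $|z| < 4$ across 20 statistics;
* covariance recovery: 20 replicates at $J = 100$, $I = 3$, $L = 2$,
  6000 iterations each, fitted with the interaction term on data
  simulated with it; 95% credible intervals for every $\Sigma_t$ and
  $R_e$ element cover the truth in at least 80% of replicates;
* CV2 law: 1000 partitions at $J = 100$, $I = 3$ — mean line-inclusion
  frequency 0.6, environments uniform;
* engine comparison: $J = 50$, $I = 3$, $L = 2$, $p = 200$, 10
  partitions, strong simulated genotype-by-environment signal (residual
  covariance $0.2 I + 0.05$, so stratum heritabilities around 0.6–0.9);
  under these conditions the Bayesian model with the interaction term
  attains the highest cross-stratum mean accuracy of the four engine
  variants, the direction expected when the data-generating process
  contains exactly that interaction. The comparison uses a reduced
  network grid (units $\{32, 64\}$, 60 epochs, 1–2 layers) — tuning 108
  configurations per partition is a real-data analysis setting, not a
  validation necessity.

## Known limitations

* Identifiability: without the interaction term, the genetic trait
  *covariance* is informed only by the $I$ within-line replicates; at
  $I = 3$ its posterior is wide and prior-sensitive, and fixed-truth
  frequentist coverage of credible intervals can fall below nominal even
  though the sampler is exact. With the interaction term (and its
  $IJ$-row effect matrix) the covariance posteriors are much better
  identified.
* The uncentred $G_g = WW^\top/p$ contains a large shared component
  (lines are positively related on average), which is absorbed by the
  environment means; genomic prediction rests on the centred part of the
  relationship matrix.
* The network engine offers no uncertainty quantification, and its
  selected hyperparameters are data-dependent — rerunning with another
  seed can select a different grid point with similar validation loss.
* No CV1/CV0 schemes (untested lines / untested environments), no
  marker-effect models, no non-Gaussian traits.

## A minimal session

```{r example, eval = FALSE}
sim <- simulate_dataset(J = 50, I = 3, L = 2, p = 200, seed = 1)
cmp <- run_comparison(sim$data, n_partitions = 10,
                      bmtme_control = list(n_iter = 2000, burn_in = 1000),
                      grid = mtdl_grid(units = c(32, 64), epochs = 60,
                                       layers = 1:2),
                      h2 = sim$truth$h2, seed = 2)
cmp$overall
```
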