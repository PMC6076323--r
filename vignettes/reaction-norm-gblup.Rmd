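---
title: "Reaction-norm GBLUP for multi-environment genomic prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reaction-norm GBLUP for multi-environment genomic prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gxegblup)
```

## The prediction problem

Breeding programs evaluate candidate lines in multi-environment trials
(METs): the same set of lines is grown across combinations of year,
location and management, and the trait of interest (yield, flowering time,
seed weight, ...) is recorded per line and environment. Genomic selection
replaces part of this phenotyping with predictions from genome-wide
markers. Because genotype-by-environment (G×E) interaction re-ranks lines
across environments, prediction models that carry an explicit interaction
structure can outperform main-effects models — and how much they help
depends on *which* prediction problem the breeder faces.

`gxegblup` implements this workflow end to end: genomic relationship
matrices from SNP dosages, a registry of thirteen reaction-norm GBLUP
models, Bayesian variance-component estimation, and within-environment
accuracy assessment under three cross-validation schemes.

## The model family

All models are sub-models of the full reaction norm for the phenotype
$y_{ij}$ of line $j$ in environment $i$:

$$y_{ij} = \mu + E_i + L_j + g_j + EL_{ij} + Eg_{ij} + e_{ij}$$

with independent Gaussian random effects:

* $E_i \sim N(0, \sigma^2_E)$ — environment main effect;
* $L_j \sim N(0, \sigma^2_L)$ — line main effect, kept alongside the
  genomic term to absorb non-additive genetic effects the linear kernel
  does not capture;
* $\mathbf{g} \sim N(0, \mathbf{G}\sigma^2_g)$ — genomic value, with
  $\mathbf{G} = \mathbf{XX}'/p$ the genomic relationship matrix over
  centered, standardized marker dosages (GBLUP). This is the kernel form
  of a ridge regression on markers, $g_j = \sum_m x_{jm} b_m$ with iid
  normal marker effects;
* $\mathbf{EL} \sim N(0, (\mathbf{Z}_L\mathbf{Z}_L') \circ
  (\mathbf{Z}_E\mathbf{Z}_E')\,\sigma^2_{EL})$ — the *naive* interaction:
  line-by-environment cell effects with identity line covariance;
* $\mathbf{Eg} \sim N(0, (\mathbf{Z}_g\mathbf{G}\mathbf{Z}_g') \circ
  (\mathbf{Z}_E\mathbf{Z}_E')\,\sigma^2_{Eg})$ — the *marker-informed*
  interaction, where $\circ$ is the Hadamard (element-wise) product of the
  genomic and environment incidence covariances;
* iid residuals $e_{ij} \sim N(0, \sigma^2_e)$.

The registry (`enumerate_models()`) crosses the structural choices with
three marker platforms — a dense GBS-style panel (G1), a sparse
DArTseq-style panel (G2) and their combination (G3) — giving thirteen
models: the baseline `E+L`, three genomic main-effects models `E+L+Gk`
(four main-effects models in total), three naive-interaction models
`E+L+Gk+LE`, and six marker-informed interaction models `E+L+Gk+GkE`
and `E+L+Gk+GkE+LE`.

`build_kernels()` materializes each model as record-level covariance
kernels: $K_E = Z_EZ_E'$, $K_L = Z_LZ_L'$, $K_G = Z_g G Z_g'$,
$K_{LE} = K_L \circ K_E$ and $K_{GE} = K_G \circ K_E$. By the Schur
product theorem each Hadamard kernel is positive semidefinite. On a
complete single-replicate layout $K_{LE}$ is the identity — which means
the naive interaction and the residual are confounded there; their *sum*
is identified, their split is driven by the prior. This is a property of
the design, not of the implementation, and is why self-prediction
invariants are stated for models without cell-level interaction terms.

## Genomic relationship matrices

`build_grm()` centers each marker column and divides by its *population*
standard deviation (divisor $n$, not $n-1$) before forming
$\mathbf{G} = \mathbf{XX}'/p$. With this convention
$\mathrm{trace}(\mathbf{G})/n = 1$ holds exactly, which we use as a
structural identity test. QC (`filter_and_impute()`) removes markers
above a missingness threshold (default 0.2) or below a minor-allele
frequency of 0.01, drops monomorphic markers, and mean-imputes the
remaining missing dosages — the minimal deterministic imputation, chosen
because the platforms differ mainly in missingness and density rather
than in error structure. Both thresholds are configurable.

A note on marker informativeness summaries: the biallelic polymorphism
information content $\mathrm{PIC} = 1 - p^2 - q^2 - 2p^2q^2$ implemented
in `compute_pic()` is bounded by 0.375 (at $p = 0.5$). Values up to 0.5
sometimes quoted for dense sequencing panels correspond to expected
heterozygosity $2pq$, a different statistic; this package implements the
standard PIC formula only.

## Fitting: a multi-kernel Gaussian Gibbs sampler

`fit_gibbs()` estimates all variance components and effects jointly. Each
kernel effect $u_k \sim N(0, \sigma^2_k K_k)$ is reparameterized through
the eigendecomposition $K_k = U\,\mathrm{diag}(d)\,U'$ as
$u_k = U\,\mathrm{diag}(\sqrt{d})\,\delta_k$ with iid
$\delta_k \sim N(0, \sigma^2_k)$; because $U$ is orthonormal over the full
record set, the full conditional of $\delta_k$ is diagonal and the sampler
needs only two matrix-vector products per kernel per iteration.
Eigenvalues below $10^{-8}$ of the largest are truncated; diagonal kernels
are detected and handled without factorization.

Held-out records are handled by data augmentation: their responses are
drawn from the current model at every iteration, which leaves the
posterior over observed data untouched while making the eigendecomposition
independent of the train/test partition, so it is computed once per model
and reused across all folds and repeats. The reported prediction for any
record is the posterior mean of its genetic value
$\mu + \sum_k u_{k}$; for records with no kernel covariance to the
training set this collapses to the posterior mean of $\mu$, as it should.

Priors and defaults (all configurable):

* variance components: scaled-inverse-chi-square with $df_0 = 5$; the
  scale is set so the prior mode splits half the response variance
  ($R^2 = 0.5$) equally across the kernels, with the other half on the
  residual — a standard weakly informative default for multi-kernel
  Gaussian regression;
* $\mu$: flat-prior fixed intercept with a normal full conditional;
* MCMC: 12 000 iterations, 2 000 burn-in, thinning 5 by default. The
  cross-validation studies in the tests use shorter chains (1 200–4 000
  iterations) at the reduced problem sizes stated below, where the
  posterior is well explored much earlier; posterior-mean predictions are
  insensitive to chain length well before the default.

`blup_known_variance()` is the closed-form mixed-model oracle for the same
family: with known variances, $V = \sum_k \sigma^2_k K_k^{(train)} +
\sigma^2_e I$, $\hat\mu$ the GLS mean and predictions
$\hat\mu + \sum_k \sigma^2_k K_k[r, \cdot]\,V^{-1}(y - \hat\mu)$. The test
suite checks the sampler against this oracle at the posterior-mean
variances (at moderate $n$ the variance posterior has non-negligible
spread, so agreement is stated at the posterior mean rather than at the
generative values) and against exact closed forms (shrinkage toward the
mean for a single identity kernel).

## Cross-validation schemes

* **CV0** — leave one environment out entirely; deterministic, one run,
  so no SD is reported. Mimics prediction of an untested environment.
* **CV1** — line-level five-fold CV, all records of a line held out
  together; 20 repeats give 100 runs. Mimics newly developed lines.
* **CV2** — record-level five-fold CV; a line is typically observed in
  some environments and predicted in others (sparse testing). Folds are
  stratified by environment so every environment has test records in
  every run and the within-environment correlation is always defined —
  the splitting text for this scheme can be read line-wise or
  record-wise; the record-wise reading is adopted because it is the one
  that yields sparse testing.

Partitions are generated from a master seed, independent of the model, so
every model is evaluated on identical splits; they can be exported and
re-imported as CSV for exact replay. Accuracy is the Pearson correlation
between observed phenotypes and predicted genomic values computed *within*
each environment's test records (trial basis); a run's summary is the mean
over environments, and a cell's mean/SD are taken over runs (sample SD,
$n-1$; reported SD could alternatively be taken across environments — the
across-runs convention is used because CV0, with one deterministic run,
then naturally reports no SD). Correlations that are undefined (constant
predictions, fewer than three pairs) are excluded and counted rather than
zero-filled: a model with no line-differentiating term predicts
within-environment constants up to sampler noise, and a pseudo-correlation
of that noise would be a Monte-Carlo artifact.

## The synthetic-data generator

No real genotype or phenotype data ship with the package; the generator
(`sim_config()`, `simulate_dataset()`) emulates the structure of a
320-line chickpea MET: 9 environments from the year-by-location-by-
management design (`default_trial_design()`), 8 traits, a dense
high-missingness panel (88 845 SNPs, 30% missing calls) and a sparse
low-missingness panel (1 568 SNPs, 5%), marker dosages drawn
binomial(2, $p_m$) with $p_m$ uniform on [0.05, 0.5]. Phenotypes follow
the full reaction-norm model above with the generative $\mathbf{G}$ built
from the simulated markers. The default variance fractions
$(\sigma^2_E, \sigma^2_L, \sigma^2_g, \sigma^2_{EL}, \sigma^2_{Eg},
\sigma^2_e) = (0.15, 0.10, 0.25, 0.10, 0.15, 0.25)$ describe a moderately
heritable trait with substantial but not dominant G×E — a realistic
mid-point for MET traits; trait distributions are otherwise free
parameters, not calibrated to any crop.

The marker-informed interaction is drawn as one independent
$N(0, \sigma^2_{Eg}\mathbf{G})$ vector per environment, which realizes the
Hadamard covariance exactly on a complete layout without factorizing a
records-by-records matrix. All drawn effects are returned in a truth
sidecar keyed by (env, line, trait) to support parameter-recovery tests.

What the generator does *not* emulate: linkage disequilibrium and genetic
map structure (markers are independent), population structure and
subpopulation divergence, platform-specific genotyping error,
heteroscedastic or non-Gaussian traits, and incomplete/unbalanced trial
layouts (records can be dropped downstream to create them). Passing tests
therefore demonstrate correctness of the machinery and qualitative
behavior of the schemes — not calibrated accuracy levels for real crops.

## Problem sizes used in the test suite

The package's studies are desk-scale by design: oracle equivalence uses
150 records (30 lines × 5 environments) with 30 000 iterations; parameter
recovery uses the full 320 × 9 layout with 2 000 markers and 3 seeds;
the scheme-ordering and interaction-benefit studies use 20 replicate
datasets of 100 lines × 5 environments × 500 markers with short chains.
These sizes give stable Monte-Carlo behavior for the properties being
checked while keeping a full run of the suite comfortable on a laptop.

## Known limitations

* REML/EM fitting is not provided; the Gibbs sampler is the only
  estimation path (the closed-form BLUP requires known variances).
* Environmental covariables are not modeled — environments enter only as
  identifiers, so CV0 predictions for a new environment center on the
  population mean for that environment's lines.
* Single-trait analyses only; traits are modeled independently.
* On complete single-replicate layouts $\sigma^2_{EL}$ and $\sigma^2_e$
  are confounded (identity kernels); their sum is well identified.
* With unlinked simulated markers $\mathbf{G}$ is within $O(1/\sqrt{p})$
  of the identity, so $\sigma^2_L$ (identity covariance) and
  $\sigma^2_g$ ($\mathbf{G}$ covariance) are only weakly separable: the
  posterior pins their sum but spreads mass along the $L$/$g$ ridge.
  Parameter-recovery results for the individual components should be read
  with this in mind; real panels with linkage disequilibrium and family
  structure give $\mathbf{G}$ far more contrast and a cleaner separation.
* The naive sampler treats one fold at a time; the 13-model × 3-scheme ×
  multi-trait full factorial at publication scale is embarrassingly
  parallel but the package itself runs serially.
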