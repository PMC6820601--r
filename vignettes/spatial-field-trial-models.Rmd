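---
title: "Spatial models for field trials: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial models for field trials: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spatfield)
```

## The statistical problem

Early-stage variety trials evaluate many lines with one or two plots each,
so plot-level environmental variation — much of it spatially smooth — can
easily dominate the genetic signal. `spatfield` implements a latent
Gaussian model for such trials,

$$y(s_i) \mid \eta(s_i), \sigma^2_e \sim N(\eta(s_i), \sigma^2_e), \qquad
\eta(s_i) = \beta_0 + \mathbf{w}_i'\boldsymbol\beta + g_j + x(s_i),$$

and studies how much modelling $x(s_i)$ improves estimated breeding values,
with and without genome-wide markers, on simulated wheat breeding
programmes, on multi-trial data with shared hyperparameters, and on the
irregular Nelder wheel spacing design used in tree breeding.

## Spatial components

* **Row+Col**: $x_i = r_i + c_i$ with independent Gaussian row and column
  effects; captures drilling/management striping but not smooth 2-D trends.
* **AR1$\otimes$AR1**: the separable first-order autoregressive field on the
  plot lattice. We parameterize by the marginal variance $\sigma^2_x$ (the
  quantity carrying the variance prior) and the two autocorrelations, so the
  covariance is $\sigma^2_x (R_r \otimes R_c)$ with correlation
  $\rho_r^a\rho_c^b$ at lag $(a, b)$. The precision is the Kronecker product
  of tridiagonal AR1 precisions, with an analytic log-determinant. Lags are
  integer row/column steps; physical spacing is ignored, which is the
  convention for this model.
* **Matérn**: a stationary Gaussian random field with covariance
  $$C(d) = \frac{\sigma_s^2}{2^{\nu-1}\Gamma(\nu)} (\kappa d)^\nu
  K_\nu(\kappa d), \qquad \kappa = \sqrt{8\nu}/\rho,$$
  where the range $\rho$ is the distance at which correlation falls to about
  0.1 (0.14 exactly at $\nu = 1$). Smoothness is fixed at $\nu = 1$
  ($\alpha = \nu + d/2 = 2$ in the SPDE formulation); it is exposed as a
  parameter only for testing, because trial data cannot identify it. The
  Matérn model uses physical coordinates, so the 2:1 column-to-row spacing
  of long narrow cereal plots is respected by scaling coordinates, not by an
  anisotropic covariance.

At the problem sizes this package targets (up to a few thousand plots) the
Matérn field is handled with its exact dense covariance; Cholesky
factorizations at this scale are cheap and exactly testable. A
finite-element SPDE backend (`matern_spde`, `spde_precision()`) builds the
sparse Markov approximation on a structured triangulated mesh and is
validated against the exact covariance (maximum correlation error below
0.05 for mesh spacing $\rho/5$ and a boundary extension of one range); it is
the route to much larger or irregular problems. Mesh construction uses a
regular grid over the bounding box extended by one range on each side —
the extension controls the inflation of boundary variance under the Neumann
condition.

## Genetic components

Line effects $g_j$ decompose into additive effects $a_j$ and a residual
line effect $n_j \sim N(0, \sigma^2_n)$. Additive effects can be modelled as
$\mathbf{a} \sim N(0, \mathbf{A}\sigma^2_a)$ with the VanRaden relationship
matrix $\mathbf{A} = \mathbf{Z}\mathbf{Z}'/k$, $k = 2\sum_l q_l(1-q_l)$, or
equivalently through marker effects $\mathbf{a} = \mathbf{Z}\mathbf{u}$,
$\mathbf{u} \sim N(0, \mathbf{I}\sigma^2_u)$ with $\sigma^2_a = k\sigma^2_u$
— an identity the test suite checks to $10^{-6}$. Because the iid prior on
marker effects is rotation invariant, the marker matrix can be compressed by
SVD to its leading principal components ($\mathbf{Z}^* = \mathbf{Z}
\mathbf{V}[, 1\!:\!p^*]$) with no change to fitted values at full rank and
negligible change at the 95%-variance rule; this is what makes dense marker
data tractable inside a sparse-precision framework. Marker matrices are
centred by default and optionally scaled; missing dosages are imputed with
the column mean; non-genotyped lines can be appended to a relationship
matrix as an unrelated identity block. For out-of-sample prediction the SVD
is taken over the combined training and prediction lines — an unsupervised
operation that uses no phenotypes, so there is no leakage.

## Priors and their interpretation

* Variances (residual, line, marker-component, spatial): inverse-gamma with
  shape 1 and scale $5\times 10^{-5}$ — proper but weak, with density
  $\propto v^{-2}e^{-\beta/v}$. Its pull toward small values means that
  weakly identified variance components (for example the line variance when
  the realized heritability is a few percent) shrink essentially to zero;
  posterior means of the line effects then remain useful for *ranking* but
  their scale is strongly shrunk. This behaviour is inherent to the prior
  choice, and is visible in the CRPS of the weakest models.
* Intercept and covariate effects: Gaussian with variance 1000.
* Autocorrelations: the Fisher-type transform $z = \log((1+\rho)/(1-\rho))$
  carries a Gaussian prior. Two conventions coexist for its spread: a
  standard deviation of 0.15 confines $\rho$ to roughly $(-0.15, 0.15)$
  (97.5% quantile $\tanh(1.96 \cdot 0.15/2) \approx 0.146$ — the identity
  `rho_prior_quantile()` reproduces), which is incompatible with the
  autocorrelations near 0.8 that separable models routinely estimate in
  field trials. The model therefore uses the software-default convention of
  a Gaussian with mean 0 and *precision* 0.15 (sd $\approx 2.58$), which is
  genuinely weak. We verified by exact marginal-likelihood computation that
  under the sd-0.15 reading the AR1$\otimes$AR1 model collapses to a
  degenerate mode (residual variance at the prior mode, $\rho \approx 0.3$)
  even on data generated with $\rho = 0.8$.
* Matérn $(\log\kappa, \log\tau)$: independent Gaussians with unit variance,
  centred so that the prior mean corresponds to a range of one fifth of the
  field diameter and unit marginal variance. This is the package's concrete
  reading of "priors that scale automatically with the field": it keeps the
  prior weakly informative regardless of the coordinate units.

## Inference

With a Gaussian likelihood the conditional posterior of the latent field at
fixed hyperparameters is exactly Gaussian: precision
$Q_{post} = Q_{prior}(\theta) + A'A/\sigma^2_e$, mean
$Q_{post}^{-1}A'y/\sigma^2_e$. The test suite verifies this against an
independent generalized-least-squares oracle to $10^{-8}$, so the only
approximation left is the exploration of the hyperparameter posterior
$\pi(\theta \mid y)$, known in closed form up to a constant.

The mode is found by BFGS on the unconstrained scale (log variances,
transformed correlations), starting from log(var(y)/number of variance
components), $\rho = 0$, and a Matérn range of a quarter of the field
diameter, with convergence tolerance $10^{-8}$ on the relative objective
(loosened to $10^{-6}$ inside the large study loops, where fits are also
warm-started from the previous replicate's mode) and at most 200 iterations;
non-convergence is an error, never silently accepted. Three integration
strategies are available: empirical-Bayes plug-in (`"eb"`, the default for
the study loops), a tensor grid of three points per dimension scaled by the
Laplace standard deviations (`"grid"`, for up to 4 dimensions), and a
CCD-style design (mode plus two scaled axis points per dimension) above
that. Latent marginals are posterior-weighted mixtures over the integration
points. Hyperparameter intervals come from the Laplace curvature on the
unconstrained scale, transformed exactly through the monotone maps; derived
quantities (range, $\sigma^2_s$) use the delta method on the joint
curvature. Models with more than 20 hyperparameters are refused and more
than 10 draw a warning, reflecting the accuracy limits of low-dimensional
numerical integration.

Numerical safeguards: any covariance Cholesky that fails receives an
escalating diagonal jitter starting at $10^{-10}$ of the mean diagonal;
transformed correlations are clamped to $\pm(1 - 10^{-8})$; non-finite
hyperparameter objectives during line search are replaced by a large
penalty so the optimizer retreats instead of crashing. Ranking ties in
`top_capture()` break by stable original order.

## The breeding-programme simulator

The generator emulates a wheat programme: a genome of 21 chromosomes
carrying SNP markers and separate QTL (defaults 100 + 100 per chromosome; a
flag scales to 1000 + 1000), fully inbred founders with allele frequencies
drawn uniformly on (0.1, 0.9) to avoid monomorphic markers, 100 crosses
among 50 parents with 100 doubled haploids each, phenotypic headrow
selection of the best 1000 into a two-location preliminary yield trial
(plot $h^2 = 0.25$), advancement of the best 100 and recycling of the best
50 as parents. Recombination follows a Haldane model with one expected
crossover per Morgan on 1-Morgan chromosomes with equally spaced loci — map
detail beyond that does not move variance-structure results. QTL effects
are Gaussian, rescaled to the target genetic variance; only the variance
scale matters to the Gaussian analysis models.

Two choices deserve emphasis:

* **Heritability anchoring.** `h2_anchor = "initial"` (default) derives the
  residual variance once from the genetic variance of the first
  doubled-haploid cohort, as programme simulators that set the error
  variance at burn-in start do. Selection then erodes the genetic variance,
  so the *effective* plot heritability in the recorded year is well below
  0.25 (typically 0.05–0.08 after ten cycles) — which is what makes
  breeding-value accuracy in the recorded trial modest and spatial
  correction valuable. `"current"` re-anchors each year so the cohort-level
  heritability stays exactly 0.25. Realized $h^2$ is always reported
  alongside study results.
* **Headrow heritability.** The headrow stage has no stated heritability;
  we use plot $h^2 = 0.1$, the standard value for visual single-plot
  selection in this literature.

Trial phenotypes sum year, location, genetic, spatial and plot-residual
effects; year and location effects have variance equal to the total
environmental plot variance $\sigma^2_e$, which is split as
$\text{prop}\cdot\sigma^2_e$ spatial (Matérn with range 10 or
AR1$\otimes$AR1 with $\rho = 0.8$, itself a range of about 10 lags) and
$(1-\text{prop})\cdot\sigma^2_e$ independent noise, with prop in
$\{0, 0.5, 0.75\}$. The partition is defined on model variances; a
Monte-Carlo test at 200 replicate fields checks the realized pooled share to
$\pm 0.02$ using mean squares (within-field correlation biases the naive
sample variance). Phenotypes are standardized before analysis — pooled over
locations within a year for the simulation study, per trial for
single-trial fits, globally for multi-trial fits.

What the generator does *not* emulate: dominance and epistasis,
genotype-by-environment interaction beyond independent location fields,
non-Gaussian phenotypes, and management/design artefacts (serpentine
harvesting, block edges). Passing tests therefore show that the estimators
behave correctly under the stated stochastic model, not that real trials
satisfy it.

## Evaluation

Estimated breeding values are the posterior means of the genetic component
that the linear predictor actually carries: the iid line effect in models
without markers, the marker component $\mathbf{z}^{*\prime}_j\mathbf{u}^*$
with markers (also the predictor for unphenotyped genotyped lines). Scores:
Pearson correlation with the true breeding values (on the standardized
scale, centred at the relevant cohort mean), the Gaussian closed-form CRPS
averaged over lines within a replicate and then over replicates, and the
number of the true best `n_top` lines among the estimated best `n_rank`
("best" = largest, as for yield). Study tables report per-cell means with
standard errors over replicates.

## Problem sizes used by the tests

The exported defaults are the full study conditions (two 50×20-plot
locations, 1000 PYT lines, 19 burn-in years, $p^* = 500$, 1000 prediction
lines, 100 replicates behind the `n_reps` setting). The test and acceptance
runs use `desk_study_config()`: 10 replicates of a proportionally reduced
programme — 20 crosses × 25 doubled haploids, 200 PYT lines in two 20×10
fields, 10 burn-in years, genome 21 × (100 SNP + 100 QTL), $p^* = 100$, 200
prediction lines, top-10-in-20 capture — chosen so a full grid of 240 fits
completes in a few minutes on one core. Generator *conditions*
(heritability, variance partition, ranges, spacing ratio) are unchanged. At
this field size the correlations sit above the full-scale values (weaker
selection intensity leaves more genetic variance) and the NoSpatial
correlation drifts upward by roughly 0.04–0.06 as the spatial proportion
grows, because with a range of 10 on a 20-unit field a sizeable share of the
spatial field is absorbed by the location mean; both are reported by the
acceptance script rather than calibrated away. The model *ordering* —
NoSpatial ≈ Row+Col < AR1$\otimes$AR1 ≈ Matérn under spatial variance, all
models equal without it, markers helping everywhere — is stable across
scales and is what the acceptance suite asserts.

The Nelder wheel experiment is run at its natural size (10 rings × 30
spokes, inner radius 10, ring factor 1.15; intercept 10, density effect 10,
spatial variance 0.5, range 10, residual variance 0.5) over 20 seeds; the
multi-trial comparison uses four 12×6 trials in two hyperparameter groups
over 4 seeds inside the acceptance suite and a 20×10 configuration
elsewhere.

## Known limitations

* Hyperparameter intervals are Laplace-based; strongly skewed posteriors
  (small trials, variance components near zero) are summarized less
  faithfully than by a full marginal computation.
* The dense Matérn path scales as the cube of the number of distinct plot
  locations; beyond a few thousand plots the SPDE backend is the realistic
  route.
* The inverse-gamma default prior shrinks weakly identified variance
  components hard; informative alternatives (e.g. penalized-complexity
  priors) are deliberately out of scope.
* Single-phenotype, Gaussian-likelihood models only; no pedigree
  relationship matrices, no core/non-core GRM partitioning, no area-level
  observations.
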