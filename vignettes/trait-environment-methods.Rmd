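---
title: "Methods: trait spectra, gap-filling and climate-soil variance partitioning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trait spectra, gap-filling and climate-soil variance partitioning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models behind `traitscape`, the tunable
parameters and their defaults, what the synthetic-data generator does and
does not emulate, and the numerical choices made where the design was
genuinely open. It states no empirical result that the package's tests and
acceptance script do not themselves compute.

## 1. The analysis in one paragraph

Trait observations (17 traits, sparse, taxonomically structured) are
gap-filled by hierarchical probabilistic matrix factorization, quality
controlled by a z-score rule, and aggregated twice: species medians per
ecoregion (A1), then ecoregion medians of species medians (A2). The A1
table yields the trait correlation structure (complete-linkage clustering,
correlation-matrix PCA) and latitudinal gradients of the component scores.
The A2 table, joined with observation-weighted means of 21 climate and 107
soil variables, yields (a) a per-trait decomposition of cross-validated
ridge-regression r² into joint and independent climate and soil effects,
and (b) a redundancy analysis of all traits on climate + topsoil
predictors.

## 2. Gap-filling model

With species `s` and traits `t` on the zlog scale (natural log, then
`z = (x - x̄)/s.d.` per trait), the model is

```
X[s,t] ~ N(u_s' v_t, 1/tau)
u_s ~ N(g_genus(s), sigma2 I),  g ~ N(f_family, sigma2 I),
f ~ N(m, sigma2 I),             m ~ N(0, sigma2 I),  v_t ~ N(0, sigma2 I)
```

All full conditionals are Gaussian, so the sampler is plain Gibbs. Design
choices, made because hierarchical-factorization protocols leave sampler
internals to the implementation:

* **Hyper-variances fixed** at `prior_var = 1` rather than sampled. The
  taxonomy acts purely as a shrinkage chain; sampling the variances adds
  mixing cost without changing what the tests verify.
* **Noise precision fixed** at `tau = 4` (residual s.d. 0.5 on the zlog
  scale). Trait tables that are z-standardized and low-rank have most
  variance in the signal; precisions 2–8 performed similarly on rank-3
  synthetic data and 4 was fixed before the acceptance thresholds were run.
* **Schedule**: up to 1000 iterations, burn-in
  200, every 20th draw retained; imputations are means over retained draws
  and the per-cell draw s.d. is the reported confidence.
* **Splits**: observed cells are split 0.8/0.1/0.1 into train/test/
  validation. Descriptions of this protocol are ambiguous about whether the
  test split participates in optimization; here it is monitored and logged
  but never used in updates, and the validation split alone drives early
  stopping. The ambiguity is recorded, not silently resolved.
* **"Stable RMSE"** has no canonical definition; here: `|ΔRMSE| < 1e-4` between
  consecutive iterations, for 5 consecutive iterations, and stopping is
  only permitted once at least one draw has been retained. With a
  stochastic sampler the per-iteration validation RMSE fluctuates at
  Monte-Carlo scale, so on realistic sizes the cap of 1000 iterations
  usually binds first; the mechanism is still exercised by tests with a
  loose tolerance.
* **QC ordering**: the pipeline imputes first, then applies the z-filter to
  observed and imputed cells alike (config switch `qc.filter_observed_only`
  restricts it to observed cells). Imputing before filtering keeps the
  maximum number of species; applying the filter to imputed cells as well
  is the conservative choice.

## 3. Aggregation

Medians use the standard sample median (mean of the two central values for
even counts). The representative latitude of an A1 row is the mean of the
contributing observation latitudes; there is no single canonical choice of
which latitude attaches to a species-by-ecoregion point, and an ecoregion
centroid variant is a natural alternative. Ecoregion inclusion is
strict: `n_species > 20` and `n_species / richness > 0.01`. Environment
variables are averaged over observation-linked locations; densely sampled
locations weigh more, so the environment summaries reflect where the trait
data actually come from.

## 4. Trait structure

* Correlations: absolute Pearson, pairwise complete, on the natural-log
  scale for positive traits. Raw-scale correlations are also supported
  (`log_scale`); log is the default for consistency with the PCA.
* The one signed trait (a leaf δ15N analogue) cannot be logged; it enters
  z-standardized on the raw scale (`signed_traits`), with the choice logged.
* Clustering: complete linkage on `d = 1 − |r|`; groups are connected
  components after cutting *strictly below* the threshold (default 1.0), so
  traits whose best correlation is exactly 0 stay separate.
* PCA: correlation-matrix PCA (centre + unit variance) of the log traits;
  each component is oriented so its largest-magnitude loading is positive.
* Axis count: legacy sequential-Bonferroni dimension tests are replaced
  by a permutation test — column-wise independent permutations give the
  null distribution of each component's variance fraction, axes are tested
  in order with a Holm step-down threshold `alpha/(K − k + 1)` and counting
  stops at the first failure. Rationale: same inferential target, no
  dependence on a specific legacy implementation; the default retained-axes
  override (5) is available where the permutation test is not wanted.
* Latitude fits: OLS of a score on |latitude| over all A1 rows, and over
  bin means with `bin = floor(|lat|)` (regressing bin mean score on bin
  mean |lat|).

## 5. Climate/soil variance partition

Each predictor block is reduced to its first 20 principal components.
Reduction is computed **once on the full table**, not per training fold:
it is unsupervised with respect to the response and keeps the meaning of
"20 components" stable across folds; a per-fold variant would be a natural
extension and the choice is documented here as genuinely open.

Ridge regression is implemented in closed form via SVD of the standardized
training predictors, minimizing `||y − Xb||² + λ||b||²`. At `λ = 0` this
is exactly OLS (min-norm on rank-deficient inputs), which the oracle tests
exploit. The λ grid is log-spaced over four decades below `max|X'y|`
(100 values by default); λ is chosen per outer-training set by inner
10-fold cross-validation minimizing mean squared error (the common
default).

The holdout r² is the **squared Pearson correlation** of concatenated
out-of-fold predictions versus observations, not
`1 − SSE/SST`; the two differ, and the correlation form is what makes
negative independent effects interpretable. The same outer-fold assignment
is shared by the climate-only, soil-only and combined fits within a
repetition, so the decomposition identities hold exactly per repetition
and are inherited by the means. With exactly two predictor groups,
hierarchical partitioning collapses to inclusion–exclusion over the three
fits. Display shares split the joint effect equally; a negative
independent effect is not drawn: its bar shows only the joint half.

Degenerate guard: if concatenated predictions are constant (or the
response is), the correlation is undefined and r² is reported as 0 with a
flag.

## 6. Redundancy analysis

`fit_rda` is the textbook two-step: multivariate least squares of the
(centred, by default scaled) trait matrix on standardized predictors, then
an SVD of the fitted values; eigenvalues are the constrained axis
variances. Predictors are restricted to the topsoil layer upstream and
pruned by iteratively removing the highest-VIF predictor while any
VIF > 20, reporting whether the final model reached VIF < 10. Because
reported RDA axis percentages frequently leave their denominator
ambiguous, both conventions are always reported: fraction of total response variance and
fraction of constrained (fitted) variance. Axes are oriented so the
largest-magnitude predictor score is positive; displayed scores are scaled
by the square roots of the eigenvalues, raw eigenvectors are also emitted.

## 7. The synthetic world

The generator's world, fixed once:

* Ecoregion latitudes uniform on [0°, 70°] absolute, random hemisphere —
  matching the latitudinal span of the real data. The latitude factor L is
  standardized −|latitude| (size declines poleward).
* The fertility factor F is drawn independently of L and then
  orthogonalized against L *weighted by the per-ecoregion sampling effort*
  before standardization. Without this, the heavy-tailed sampling weights
  (the Europe-bias analogue) induce a sampling correlation between the two
  factors of order 0.1, which leaks latitude signal into the economics
  axis — an artefact of the small number of independent ecoregions, not of
  the biology being emulated.
* Soil latent `M = √w·L + √(1−w)·F` with `w = shared_latent_weight`
  (default 0.5): climate variables are affine in L, soil variables affine
  in M, each with its own loading (|loading| uniform on [0.5, 1], random
  sign) and Gaussian noise (s.d. 0.3).
* Species: assigned a home ecoregion (probability proportional to sampling
  effort); ranges add ecoregions within a 10° absolute-latitude window,
  preferring soil latents close to home. Size score = L(home) + noise,
  economics score = M(home) + noise (s.d. 0.3). Trait values are
  `exp(baseline + size·loading_size + econ·loading_econ + genus and
  species deviations + observation noise)`; the δ15N analogue stays on the
  signed linear scale. Default loadings encode the 7 size / 7 economics /
  3 weakly structured trait grouping, with economics loadings weaker so
  the size axis dominates the trait covariance as it does in real data.
* Sampling: observations per (species, ecoregion) are `1 + Poisson`;
  ecoregion effort is lognormal (heavy-tailed). Missingness, if requested,
  removes cells uniformly subject to ≥ 1 observed value per row and per
  trait column.

What the generator does **not** emulate: geographic realism (no
coastlines, biome maps or spatial autocorrelation fields), intraspecific
trait–environment covariation, non-Gaussian trait noise, correlated
missingness (real archives miss traits in blocks, by campaign), and any
climate seasonality structure within the 21 climate variables. A green
recovery test therefore establishes that the pipeline recovers the latent
structure it is pointed at — not that real archives satisfy these
assumptions.

## 8. Numerical notes

* zlog round-trips are exact to 1e−10; constant columns error, naming the
  trait.
* PCA sign convention (largest-magnitude loading positive) makes loadings
  reproducible across BLAS implementations.
* The λ = 0 ridge path reproduces OLS predictions to 1e−10; singular
  directions are truncated at `d < max(d)·1e−12` (min-norm solution).
* Partition identities are algebraic and hold to 1e−12 on every run.
* All stage seeds are spawned deterministically from one master seed
  (`spawn_seeds`), all below 2³¹.

## 9. Known limitations

* The Gibbs sampler is pure R; at archive scale (10⁵–10⁶ rows) it needs
  minutes-to-hours, not seconds. The hierarchy is fixed at
  species/genus/family plus a global mean; deeper taxonomies are collapsed.
* Early stopping on "stable RMSE" rarely triggers at realistic sizes (see
  §2); the iteration cap is the effective stop.
* Partitioning supports exactly two predictor blocks; the >2-block
  averaged-orderings formulation is out of scope, as are alternative
  learners (PLS, random forests) sometimes used as robustness checks.
* The ecoregion assignment of observations is an input column; assigning
  coordinates to ecoregion polygons is deliberately out of scope to keep
  the package download-free.
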