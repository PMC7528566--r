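---
title: "twinpath: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{twinpath: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinpath)
```

`twinpath` implements an analysis chain for twin cohorts linking polygenic
risk, eating-behavior patterns, and obesity measures: PCA-based pattern
derivation, classical-twin variance decomposition, and mediation structural
models with a clustered bootstrap. This vignette explains the statistical
models, the assumptions behind the synthetic-data generators, and the design
choices made where the design was genuinely open.

## 1. The classical twin model

The classical twin design decomposes the variance of a standardized
phenotype into additive genetic (A), shared environmental (C), dominance
(D), and nonshared environmental (E) components, using the different genetic
resemblance of monozygotic (MZ) and dizygotic (DZ) co-twins. The latent
factor correlations within a pair are 1 (MZ) and 0.5 (DZ) for A, 1 and 0.25
for D, 1 and 1 for C, and 0 for E, giving the expected pair covariances

* `var = a² + c² + d² + e²`
* `cov_MZ = a² + c² + d²`
* `cov_DZ = 0.5·a² + c² + 0.25·d²`

Assumptions inherited from the design: equal environments across zygosity
groups, no assortative mating or gene–environment interaction in the
decomposition, and — because only twins reared together are observed — C
and D cannot be estimated simultaneously (`uni_arch()` enforces this on the
generator side; `fit_univariate()` offers ACE, ADE, AE and E models but no
ACDE).

`fit_univariate()` maximizes the exact bivariate-normal likelihood of
(twin 1, twin 2) vectors over an unconstrained mean and real-valued path
coefficients that are squared in the covariance — the standard trick that
removes boundary constraints on variances. Same-sex and opposite-sex DZ
pairs are pooled as DZ (genetic correlation 0.5) after sex residualization;
sex-stratified refits are available through the CLI's `--by-sex` flag
rather than a sex-limitation likelihood.

**Confidence intervals.** Standardized shares get profile-likelihood CIs:
the share of interest is fixed, the remaining free parameters (mean, total
variance, and the split of the complementary share in three-component
models) are re-optimized, and the 95% bound solves
`2·(logLik_max − logLik_profile) = χ²₁(0.95)` by root finding. When the
lower root does not exist because the share is at or near 0, the bound is
reported as 0 (a boundary solution, flagged on the fit).

**Model comparison.** `compare_models()` computes the likelihood-ratio
statistic between nested fits on the same data (verified via a sufficient-
statistic fingerprint). Because a variance share sits on the boundary of
its space under the null, the χ² reference is conservative; this caveat is
recorded in the comparison output, and the package's calibration tests
accordingly check that the empirical size does not exceed the nominal 5%.

## 2. Bivariate Cholesky decomposition

For two traits, `fit_bivariate_cholesky()` fits an AE model in which
lower-triangular genetic paths (`a11, a21, a22`) and nonshared-environment
paths (`e11, e21, e22`) generate the within-person covariance
`Σ_w = L_a L_aᵀ + L_e L_eᵀ` and a cross-twin block `r_z · L_a L_aᵀ`
(`r_z` = 1 for MZ, 0.5 for DZ; E does not cross twins). Derived quantities:

* genetic correlation `r_a = a21 / √(a21² + a22²)`,
* environmental correlation `r_e = e21 / √(e21² + e22²)`,
* genetic share of the phenotypic covariance
  `a11·a21 / (a11·a21 + e11·e21)`,
* per-trait heritabilities.

The identity `√h²₁·√h²₂·r_a + √e²₁·√e²₂·r_e = r_p` (the model-implied
phenotypic correlation) holds algebraically for these definitions and is
asserted on every converged fit in the test suite. Solutions with a genetic
covariance share outside [0, 1] are flagged as Heywood-like rather than
truncated.

**CIs: bootstrap rather than profile.** For the univariate model the
profile CI is cheap and standard. For the bivariate model the quantities of
interest (`r_a`, `r_e`, the covariance share) are nonlinear functions of
six paths, and profiling them would require constrained re-optimization on
a curved manifold; the package instead resamples twin pairs within zygosity
groups (a family-level bootstrap, default 1000 draws, configurable) and
reports percentile intervals — a deliberate trade of the profile machinery
for an equally standard resampling interval.

A note on terminology: in an AE bivariate model the second correlation is
environmental (`r_e`); descriptions of this design occasionally call it a
shared-environmental correlation (`r_c`), which does not exist in an AE
parameterization — `twinpath` reports `r_e`.

## 3. Pattern derivation

`derive_patterns()` runs correlation-matrix PCA (eigenvalues sum to the
number of variables; loadings are eigenvectors scaled by √eigenvalue),
retains components with eigenvalue strictly greater than 1 (ties at exactly
1.0 are excluded; scree data are emitted for plotting), varimax-rotates the
retained loadings, and computes component scores.

Numerical and design choices:

* **Varimax** is implemented as the classic Kaiser pairwise-Givens
  algorithm with row (communality) normalization — normalization is
  standard practice and is recorded in the output metadata. Convergence is
  declared when a full sweep improves the criterion by `< 1e-8`;
  non-convergence after `max_iter` sweeps is an error reporting the sweep
  count. The implementation is validated against a brute-force search over
  Givens rotation angles and against `stats::varimax`.
* **Sign convention:** each component is oriented so that its
  largest-absolute loading is positive, making labels and scores
  deterministic up to column order.
* **Scores** use the regression method (`W = R⁻¹Λ` applied to standardized
  items, then re-standardized); a sign-weighted sum-score alternative is
  available behind a flag for sensitivity analyses. The scoring method is
  not dictated by the underlying procedure, so the default follows common
  software practice.
* **Variance explained** per retained component is computed from the
  rotated loadings (post-rotation redistribution); the retained total is
  invariant to rotation.
* Items are analyzed as numeric scores by default. Whether 4-point ordinal
  responses should be recoded before PCA is an open question in this kind
  of questionnaire; the generator supports quartile discretization to the
  four categories (usually/often/sometimes/seldom) via `ordinal = TRUE`,
  and the continuous default reflects how such items are usually scored.

## 4. Mediation with clustered inference

`fit_mediation()` estimates the single-mediator linear path model by two
regressions — `a` from `m ~ x`, and `(b, c)` from `y ~ m + x` — rather than
a joint-likelihood SEM fit; for a saturated linear path model the estimates
coincide, and the reported quantities (total `c + ab`, direct `c`, indirect
`ab`) are exactly these products. `total − direct − indirect = 0` holds to
machine precision on every fit and is asserted at `1e-10`.

* **Clustered errors.** Twins are analyzed as individuals, so standard
  errors use a family-clustered sandwich (CR1 small-sample correction,
  p-values on G−1 degrees of freedom with G families). A warning is issued
  below 30 families; collinear mediator and exposure (|r| > 0.99) is an
  error.
* **Bias-corrected bootstrap.** `bc_bootstrap()` resamples whole families
  (co-twins stay together, preserving the dependence), recomputes the
  standardized effects per draw, and applies the bias-corrected percentile
  method: `z₀` is the normal quantile of the fraction of bootstrap
  estimates below the point estimate; no acceleration term (BC, not BCa).
  With a median-centered bootstrap distribution (`z₀ = 0`) the interval
  reduces to the plain percentile interval, which the tests assert on a
  near-symmetric case. A degenerate (constant) bootstrap distribution is an
  error.
* **Percentage mediation** is `100 · indirect / total` from unrounded
  estimates; a display variant reproduces the convention of rounding both
  effects to two decimals before the ratio (0.06/0.29 = 20.7%, whereas the
  unrounded ratio 0.057/0.287 = 19.9%). The percentage is suppressed with
  an explanation when the indirect and total effects disagree in sign
  (inconsistent mediation).
* **Sex interactions.** `sex_interaction_test()` adds `x:sex` to the
  mediator equation and `x:sex`, `m:sex` to the outcome equation with
  clustered Wald tests; if any interaction is significant, sex-stratified
  fits are attached.

## 5. What the generators state — and what they do not

The generators are the package's ground truth and their defaults are fixed
by the cohort they emulate: twin pairs with age uniform on 31–37 years
(shared within pair), sex Bernoulli(0.56 female), MZ pairs same-sex, OS-DZ
pairs sex-discordant, and a reference mix of 527 MZ / 470 SS-DZ / 503 OS-DZ
pairs (3977 individuals in twin analyses; 949 individuals in mediation
analyses).

* `simulate_univariate_twins()` composes phenotypes as
  `a·A + c·C + d·D + e·E` from latent standard normals with the classical
  within-pair correlations, so population moments are exact by
  construction.
* `simulate_bivariate_twins()` adds cross-trait correlations `r_a` (between
  additive factors, scaled by `r_z` across twins) and `r_e` (within
  individual only); `biv_arch_from_targets()` solves `r_a`, `r_e` from a
  target phenotypic correlation and genetic covariance share.
* `simulate_items()` builds questionnaire variables from orthogonal factors
  (`Λ Λᵀ + Ψ` population correlation); the default 16-variable, 4-factor
  template loads 4 items per factor at 0.5, which puts exactly 4 population
  eigenvalues (1.75) above the retention cutoff.
* `simulate_prs_mediation()` draws a standardized exposure with within-pair
  correlation 1 (MZ) / 0.5 (DZ) — as a genetic score must have — and builds
  `M = aX + u_m`, `Y = bM + cX + u_y` with unit variances. The residual
  within-pair correlations (0.4 MZ / 0.2 DZ) and the 1/3 MZ share among
  pair families are fixed, realistic choices for moderately heritable
  traits; they affect standard errors, not point estimates. With
  `pair_fraction = 0.5`, `n_individuals = 949` maps to 633 families (316
  pairs + 317 singletons). If `c_path` is omitted, it is solved from the
  target score-outcome `R²` as `c = √R² − ab`; if both are supplied they
  must be consistent.
* `simulate_cohort()` wires these pieces into a full cohort (patterns with
  heritabilities 0.36–0.48, BMI/WC at 0.76/0.62 with genetic overlap, a
  polygenic score with `R² = 0.083` against BMI, pure-noise genetic PCs)
  for end-to-end pipeline runs.

What a green test on this world does **not** establish: robustness to
missing data beyond complete-case deletion, to non-normal or genuinely
ordinal item distributions, to sex-limitation (qualitative or quantitative)
genetic architectures, to assortative mating or zygosity misclassification,
or to selection into genotyping. Pattern scores estimated from noisy items
are attenuated relative to the latent pattern phenotypes, so pipeline-level
heritabilities of scores sit below the generating values of the latents —
visible in the end-to-end test and expected, not a defect.

## 6. Numerical choices and degenerate inputs

* Likelihoods are computed from sufficient statistics (per-group scatter
  matrices), so fit cost is independent of the number of pairs; optimization
  is Nelder–Mead followed by a BFGS polish, keeping whichever is better.
  Non-PD covariance proposals score `-Inf` and are stepped around.
* Bivariate starting values come from the moment estimator
  `G₀ = 2(C_MZ − C_DZ)` of the cross-twin covariance blocks, eigenvalue-
  floored to be positive definite before the Cholesky.
* Residualization uses a QR decomposition; rank deficiency is an error
  naming the collinear columns. Residuals are exactly orthogonal to the
  design and residualization is idempotent to 1e-10 (tested).
* The singular MZ Kronecker covariance in the generators (a rank-deficient
  but valid PSD matrix) is handled with a symmetric eigen square root
  rather than a Cholesky factorization.
* Pairing keeps the twin-order assignment as given (no re-sorting), errors
  on duplicated (family, twin order) keys, and drops incomplete pairs with
  counts reported per zygosity.

## 7. Known limitations

* No multivariate (> 2 traits) Cholesky, extended-family designs, or
  joint C+D estimation (unidentified in this design).
* No oblique rotations, ML factor extraction, or parallel analysis for
  component retention.
* Mediation is a single-mediator linear model; no multiple mediators,
  sensitivity analysis for unmeasured confounding, or longitudinal
  cross-lagged structure.
* The pipeline treats the polygenic score as an observed standardized
  column; genotype-level simulation, imputation and score construction are
  out of scope.
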