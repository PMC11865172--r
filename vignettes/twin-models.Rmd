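---
title: "Twin models for social factors and wellbeing: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Twin models for social factors and wellbeing: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the models it implements,
the assumptions they carry, and the design decisions taken where the
methodology is genuinely open. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## The biometric model

For m traits measured in both members of MZ and DZ twin pairs, the
multivariate Cholesky model decomposes the m x m phenotypic covariance into
additive-genetic (A), shared-environmental (C) and non-shared environmental
(E) parts, each parameterized as `L %*% t(L)` with L lower-triangular. The
2m x 2m covariance of a pair's stacked trait vectors has within-twin blocks
`A + C + E` and cross-twin blocks `r*A + C`, with the additive-genetic
cross-twin correlation r = 1 for MZ and 0.5 for DZ pairs, shared environment
correlating 1 in both zygosities, and non-shared environment 0. The model's
assumptions are the classical ones: additivity (no dominance or epistasis
in A), equal environments across zygosities, no assortative mating, no
gene-environment interaction or correlation. None of these are testable
inside the package and all are standard caveats for any estimate it
produces.

`fit_cholesky()` maximizes a full-information likelihood: each pair
contributes the multivariate-normal log-density of whatever subset of its
2m entries is observed, so singleton twins and partially missing trait
vectors enter via exact marginal terms. The implementation groups pairs by
(zygosity, missingness pattern) and carries per-group cross-product
matrices, making one likelihood evaluation O(#patterns * m^3) rather than
O(#pairs * m^3); the deviance is identical to direct per-pair summation
(asserted to 1e-10 in the tests against an independent `solve()`/`det()`
oracle).

Numerical choices:

* **Parameterization.** Free parameters are the m(m+1)/2 lower-triangular
  entries per included component, unconstrained; positive semidefiniteness
  of each component is automatic. The likelihood is invariant to column
  sign flips of L, so the optimum is not unique in parameters but is unique
  in the implied covariances — all reported quantities (h2, c2, e2, rg, re,
  AIC) are functions of the covariances, and a trait-order permutation test
  asserts invariance to 1e-4.
* **Means.** The default is a zero-mean model on data residualized on age
  and sex and scaled to unit variance per trait (`residualize_age_sex`,
  `standardize`); `free_means = TRUE` adds m mean parameters for raw input.
* **Optimizer.** `stats::nlminb` with relative tolerance 1e-12, 5 restarts
  (default) from a phenotypic-Cholesky start value split evenly across
  components, perturbation scale 0.2. A non-positive-definite observed
  sub-covariance during optimization returns a large finite penalty (1e10
  plus a parameter ridge) instead of an error so the optimizer can recover.
* **Nesting.** `compare_models()` fits E, then AE seeded additionally with
  the E optimum embedded (new component at zero), then ACE seeded with AE.
  This guarantees fitted deviances respect nesting monotonicity — without
  it, optimizer noise can make a richer model appear to fit worse.
* **Undefined correlations.** A trait with numerically zero genetic
  variance (diagonal of A below 1e-10) gets an NA row/column in rg rather
  than a fabricated zero.
* **Confidence intervals.** `bootstrap_biometric()` resamples pairs with
  replacement within zygosity strata (default 200 resamples), refitting
  from the full-sample optimum. Bootstrap was chosen because the
  alternative (profile-likelihood intervals) is costlier for the same
  purpose here and the CI method used for the published supplementary
  estimates is unstated; this is a documented package choice.

## The co-twin control model

`fit_mixed()` estimates the random-intercept model

    y_ij = b0 + bW (x_ij - xbar_i) + bB xbar_i + (covariates) + u_i + e_ij

for MZ complete pairs, and the pooled variant with a single exposure
coefficient for the full sample (incomplete pairs included). Because MZ
co-twins share all genes and their rearing environment, the within-pair
deviation `x_ij - xbar_i` is orthogonal to those factors; `bW` therefore
estimates the exposure-outcome association net of familial confounding,
and its attenuation relative to the pooled coefficient
(`attenuation_summary()`) is the design's confounding diagnostic. The
residual caveats are non-shared environmental confounding and measurement
error, which the design cannot remove.

Estimation profiles the variance ratio lambda = tau2/sigma2: for clusters
of size <= 2 the per-cluster covariance `sigma2 (I + lambda J)` has
closed-form inverse and determinant, so REML (default) or ML reduces to a
one-dimensional optimization over log-lambda followed by closed-form GLS.
This is exact, fast, and verified in the tests against both a dense-matrix
brute-force maximizer (1e-4) and `lme4` (1e-5 on fixed effects). Negative
variance-ratio estimates are truncated at zero and flagged (`boundary`).
Confidence intervals are Wald with the normal reference; Satterthwaite
degrees-of-freedom corrections are deliberately out of scope, a known and
minor numerical difference from mixed-model software that defaults to them
(it matters only at small n).

Standardization order was genuinely open: the convention adopted is to
z-score the outcome and the *raw* exposure over the analysis sample, then
decompose into within/between components. Standardizing the two components
separately instead would rescale bW and bB by different factors and break
the paired-difference equivalence (`bW` equals the slope of a
through-the-origin regression of within-pair outcome differences on
exposure differences — asserted to 1e-6). Binary 0/1 exposures such as
disruption indicators are left unstandardized by convention. Effect sizes
are labelled by the bands |r| >= 0.05 / 0.10 / 0.20 / 0.30 (very small /
small / medium / large); values below 0.05 are labelled "negligible", a
band the source bands leave implicit.

The full-sample model pools MZ and DZ twins with a single pair-level random
intercept (rather than stratifying by zygosity); lagged analyses regress
wave-2 wellbeing on wave-1 exposures without baseline adjustment. Both are
the simplest readings of the described design and are recorded here as
package choices.

## The synthetic-data generator

`simulate_cohort()` draws the world the estimators assume: standard-normal
genetic, shared and unique factors combined through lower-triangular paths,
MZ genetic factors shared exactly, DZ factors split sqrt(0.5)/sqrt(0.5) so
the cross-twin genetic correlation is exactly 0.5 (not an approximation),
and a wellbeing outcome `y = gamma'S + delta'g + resid_sd * eps` mixing
direct causal input with loadings on the same genetic factors that drive
the traits. When `resid_sd` is unspecified it is solved so that var(y) = 1,
which puts generating coefficients directly on the standardized scale the
estimators report.

Stated-world defaults, chosen once:

* Heritabilities in `study_config()` span 0.24-0.42 with no shared
  environment (an AE world), genetic correlations 0.6 and non-shared
  correlations 0.2 between all traits — mid-range values for adult social
  phenotypes.
* The `scenario()` worlds fix one exposure (h2 = 0.4) and vary only the
  causal/confound mix: causal (0.3, 0), confounded (0, 0.5), mixed
  (0.3, 0.3), null (0, 0). The mixed world's pooled association is
  gamma + delta * sqrt(h2) ~ 0.49 against a within-pair truth of 0.3 —
  attenuation without elimination, the qualitative signature the co-twin
  design is meant to detect.
* Demographics: same-sex pairs, ~58% female, age ~ N(63, 4.5), shared
  within pair, independent of traits — so age/sex residualization is a
  null operation in expectation and harms nothing.
* Attrition: wave-2 retention probability `plogis(0.45 + 0.33 * z(y))`,
  i.e. ~60% retention selectively favouring the satisfied; the slope
  produces a retained-minus-lost wellbeing gap of roughly a third of a
  standard deviation, matching the magnitude of selective dropout reported
  for ageing cohort studies.
* Incomplete pairs: 5% of pairs lose their second twin.
* Likert items: each item loads 0.8 on the standardized true score plus
  unique noise, mapped linearly to the response range, rounded and
  clipped. Rounding attenuates item reliability below the continuous-score
  value; this is documented, not corrected, because real item data carry
  the same coarseness.

What the generator does **not** emulate — and what a green test therefore
does not establish: non-normal trait distributions, dominance, assortative
mating, gene-environment correlation/interaction, zygosity-dependent
environments, item-level missingness patterns, and measurement
non-invariance across waves. Estimator validation here is internal
consistency: the package recovers the truth of the world its models assume.

## Scope and format decisions

* One row per individual is the canonical long format; wave-2 outcomes are
  carried as suffixed columns (`swls_w2`) rather than duplicated rows,
  matching the analysis contract (exposures at wave 1, outcome at either
  wave). An optional `wave` column is accepted and preserved on I/O.
* Configs and the simulation truth record are JSON (`jsonlite`); the
  binary disruption composite is modelled as a continuous 0/1 variable in
  the Cholesky (liability-threshold models are a non-goal).
* Scale scoring is strict complete-case (any missing item gives a missing
  score) and sums by default; reverse-keyed items are explicit
  configuration in `inst/extdata/scales.json` because negative keying is a
  property of item wording that no score range can reveal.
* The attrition comparison uses Welch's unequal-variance t test: with
  groups of unequal size and plausibly unequal variance it is the safer
  default and costs nothing.
* Heavy Monte-Carlo checks are scaled down in the test suite (2e5 pairs
  for the pair-covariance oracle, 1e5 individuals for the generator
  covariance invariant) with tolerance bands widened to match; the scaled
  n is stated in each test.
* Model-selection validation uses a 3-trait AE world: with one trait the
  ACE-vs-AE AIC margin is a boundary chi-square coin flip in a non-trivial
  fraction of replicates, while the multivariate penalty (2 * m(m+1)/2)
  makes selection sharp — and the multivariate model is the object of
  interest anyway.

## Known limitations

Wald CIs and the absence of Satterthwaite corrections make small-sample
inference slightly anticonservative. The biometric bootstrap refits from
the full-sample optimum, which can understate CI width if a resample has a
distant optimum. No sex-limitation, dominance, common-pathway or
liability-threshold models. Opposite-sex DZ pairs are rejected by the data
model by design.
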