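---
title: "Estimating usual-intake diet quality from repeated 24-hour recalls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating usual-intake diet quality from repeated 24-hour recalls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Diet-quality indices such as the Healthy Eating Index 2010 (HEI-2010) are
defined on *usual* (long-run average) intake, but large studies can usually
afford only one or two 24-hour recalls per person. A single recall is an
error-prone snapshot: day-to-day variation inflates the spread of
recall-based scores, so naive estimates of "percent of the population at the
maximum score" or "percent below a cutoff" can be badly biased even when the
population mean is about right. Worse, several HEI components (whole fruit,
greens and beans, seafood and plant proteins) are *episodic* — many people
genuinely consume them, but not on any given day — so a recall of zero does
not mean a usual intake of zero.

`heiusual` implements the standard statistical remedy: fit a latent-variable
measurement-error model to the repeated recalls, then summarize the
*modeled* distribution of usual intake rather than the raw recalls.

## HEI-2010 scoring

`score_profile()` scores a table of intake amounts. All 12 components are
energy-adjusted densities (amounts per 1,000 kcal, a ratio of fatty acids,
or percent of energy), so scores are invariant to proportional scaling of
amounts and energy. Nine adequacy components score linearly from 0 at zero
density to the maximum points at a saturation standard; three moderation
components (refined grains, sodium, empty calories) score linearly downward
between two standards; the fatty-acid ratio scores (PUFA+MUFA)/SFA between
1.2 and 2.5. The standards live in a YAML file shipped with the package
(`inst/extdata/hei2010_standards.yaml`) and are validated on load: 12
components, maximum points in {5, 10, 20} summing to 100, and moderation
standards correctly ordered. Empty calories are solid-fat kcal plus
added-sugar kcal plus the energy of alcohol beyond 13 g per 1,000 kcal.

```{r}
library(heiusual)
prof <- data.frame(
  energy = 2000, total_fruit = 1.6, whole_fruit = 0.8, total_veg = 2.2,
  greens_beans = 0.4, whole_grains = 3.0, dairy = 2.6, total_protein = 5.0,
  seafood_plant_prot = 1.6, pufa_g = 12, mufa_g = 18, sfa_g = 10,
  refined_grains = 3.6, sodium = 2.2, solid_fat_kcal = 228,
  added_sugar_kcal = 152, alcohol_g = 0)
score_profile(prof)$total  # 100: this profile sits at every maximum standard
```

## The measurement-error model

Thirteen daily variables enter the model: energy, the eight adequacy food
groups, refined grains, sodium, a solid-fat/added-sugar/alcohol aggregate
(empty-calorie fuel), and the fatty-acid quantities. Amounts are transformed
toward normality — Box-Cox with exponent 0.25, or log for strictly positive
variables — after adding half the smallest positive value to handle zeros,
then linearly rescaled so each transformed variable has variance 2 (a
numerically convenient common scale).

For person *i*, recall *j*, transformed variable *v*:

* **Amount part.** `T_ivj = x_ij' beta_v + u_iv + e_ivj`, where `x_ij`
  contains an intercept, centered age, sex, a weekend indicator, indicators
  for "reported intake was more/less than usual", a second-recall indicator,
  and heritage and field-center dummies.
* **Consumption part.** For the three episodic components, a recalled zero
  arises from a probit submodel with its own person effect; the observed
  amount is the product of the consumption indicator and the amount part.
* **Random effects.** The stacked person effects (13 amount effects plus the
  episodic probit effects) are multivariate normal with unstructured
  covariance `Sigma_b`; within-person residuals are multivariate normal with
  covariance `Sigma_e`. The full covariances are what let a single model
  propagate correlation between, say, energy and sodium into the joint
  usual-intake distribution.

Two estimators are provided:

* `me_config(method = "moments")` — a pairwise-factorized (method-of-moments)
  fit: per-variable least squares for the fixed effects, `Sigma_e` from
  within-person recall differences, `Sigma_b` from person-mean residual
  covariance minus `Sigma_e/2`, probit coefficients by GLM with the probit
  person-effect scale matched to the observed between/within concordance of
  zeros, and projection of each covariance to the nearest positive-definite
  matrix. It is fast (well under a second at n = 2,000) and is the default
  throughout the test-suite recovery checks.
* `me_config(method = "gibbs")` — a blocked Gibbs sampler over fixed
  effects, person effects, latent probit scores, and the two covariances.
  With 13-plus-dimensional unstructured covariances, weak inverse-Wishart
  priors measurably distort the weakly identified split between `Sigma_b`
  and `Sigma_e` (the determinant term pulls the between-person covariance
  down). The sampler therefore centers its inverse-Wishart priors on the
  moments estimates with a small prior weight (`prior_weight`, default 0.1,
  expressed as a fraction of the sample size); with the weight at its
  default the posterior means track the moments estimates closely while
  still providing full uncertainty quantification.

## From model to population summaries

`draw_usual()` generates `M` Monte Carlo draws of each person's usual-intake
vector: draw person effects from their posterior (or plug-in) distribution,
set recall-context covariates to their reference distribution (weekday
weight 4/7, typical-amount reporting, first-recall conditions), compute each
variable's usual intake as the *expectation over the within-person residual*
of the back-transformed amount — evaluated by 9-point Gauss–Hermite
quadrature, which is exact for the polynomial part of the integrand — and
multiply episodic amounts by the person's consumption probability.
Optionally the age covariate is fixed and sex resampled to a reference
distribution, giving age/sex-standardized summaries.

`build_pseudo_population()` scores every draw and attaches the survey design,
splitting each participant's sampling weight equally across their `M`
pseudo-rows. `summarize_pseudo()` then computes weighted component means and
percent-at-maximum (with an absolute floating-point tolerance at the
boundary), overall or for subgroups.

## Survey statistics

The survey layer is self-contained: weighted means with Taylor-linearized
standard errors (which reduce exactly to `s/sqrt(n)` on an unweighted
single-stratum design — a unit-testable identity), a Rao–Wu rescaling
bootstrap that resamples `n_h - 1` PSUs per stratum with replacement,
survey-weighted least squares with a design-based sandwich covariance
(degrees of freedom = PSUs minus strata), and joint Wald tests. Regression
of person-level HEI on covariates uses `backward_select()`: forced design
variables are never dropped, and the remaining candidates are removed one at
a time by largest Wald p-value until all fall below the stay threshold, with
every drop recorded in an audit table.

## The synthetic cohort

Because real dietary data cannot ship with the package, `generate_cohort()`
simulates a cohort with fully known ground truth: a stratified multi-PSU
design with lognormal weights, demographic covariates, and latent usual
intakes generated from the same model family the estimator assumes.
`generate_recalls()` adds within-person day-to-day noise, episodic zeros,
recall-context effects, and derived nutrient fields. `true_summaries()`
integrates the known person-level distributions (again by Gauss–Hermite
quadrature) to give the exact component means and percent-at-maximum the
pipeline should recover. The generator's defaults define the study
condition for all recovery tests and are never adjusted to make a test pass.

## Limitations

* The estimators assume the transformed amounts are conditionally Gaussian;
  heavy-tailed or multimodal intakes would violate this.
* Usual-intake draws use plug-in parameter estimates; parameter uncertainty
  is carried by the PSU bootstrap (or the Gibbs posterior), not by the draws
  themselves.
* At tight tolerances, recovery of moderation-component means at moderate
  sample sizes (n around 2,000) is limited by sampling noise in the
  covariance estimates, not by bias; see the recovery tables written by
  `analysis/03_recovery_check.R`.
* Sampling weights do not enter model fitting (a model-based estimation
  contract); they re-enter at the summary stage.
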