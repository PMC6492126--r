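---
title: "Calibrated-δ adjustment MI: model, algorithm and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrated-delta adjustment MI: model, algorithm and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calmi)
```

## The problem

Standard multiple imputation is valid when data are missing (completely)
at random. For an incomplete covariate such as ethnicity in primary-care
records, missingness plausibly depends on the unobserved value itself —
missing not at random (MNAR) — and no amount of conditioning on observed
variables fixes that. MNAR models are unidentifiable from the sample
alone; every analysis needs an extra, untestable input. `calmi`'s input is
deliberately modest and often available: the *marginal* distribution of
the incomplete covariate in the population the sample was drawn from
(census, national survey).

## Model and calibration equations

Let $x$ be the incomplete covariate ($K$ levels, level 1 the base), $y$
the fully observed binary outcome, $z$ further fully observed categorical
covariates, and $r$ the response indicator of $x$. The imputation model is
the (multinomial) logistic regression of $x$ on $(y, z)$ fitted by ML to
the complete records, giving estimates $\hat\theta$ with asymptotic
covariance $\hat U$.

A pattern-mixture factorisation allows nonrespondents to differ from
respondents by per-level intercept offsets $\delta_j$ only; the covariate
coefficients are shared. For categorical regressions with missingness
depending on $x$ (or on $x$ and $y$) this intercept-only contrast is
exactly the right correction — the respondent/nonrespondent
covariate-association parameters coincide, a property the test suite
asserts rather than re-derives.

Total probability pins down what the nonrespondents must look like:
$$p(x = j \mid r = 0) \;=\; \frac{p^{pop}_j - p(x = j \mid r = 1)\,p(r=1)}{1 - p(r=1)},$$
and the model-implied nonrespondent marginal with offsets $\delta$ is the
softmax average over the nonrespondent rows $i$:
$$\frac{1}{n_{mis}} \sum_i
  \frac{\exp(\eta_{ij} + \delta_j)}{1 + \sum_{j'} \exp(\eta_{ij'} + \delta_{j'})}.$$
The calibrated-δ adjustment solves the $K-1$ equations equating the two.
For $K = 2$ this is one strictly monotone equation solved by interval
bisection; for $K > 2$ a simultaneous nonlinear system.

If a target $p(x=j\mid r=0)$ falls outside $(0,1)$ the population figure
is arithmetically incompatible with the observed data and response rate.
`calmi` raises an error naming the level instead of clipping: clipping
would silently change the estimand of the sensitivity analysis.

## The proper-imputation algorithm

Each of the $M$ imputations runs independently:

1. draw $\tilde\theta \sim N(\hat\theta, \hat U)$;
2. draw the response proportion
   $\tilde p_r \sim N(\hat p_r, \hat p_r(1-\hat p_r)/n)$ and the
   observed-data level proportions
   $\tilde p_x \sim N(\hat p_x, \hat p_x(1-\hat p_x)/n_{obs})$;
3. in estimated-reference mode, draw
   $\tilde p^{pop} = \hat p^{pop} + \tilde z \, SE(\hat p^{pop})$,
   $\tilde z \sim N(0,1)$;
4. solve for $\delta$ using the drawn quantities;
5. draw fresh parameters $\dot\theta \sim N(\hat\theta, \hat U)$ and
   impute each missing value from the (multinomial) logistic model with
   the $\delta$ offset added to the intercept(s).

Re-solving δ from drawn (not point) quantities in every imputation is
what makes the procedure *proper*: uncertainty in the imputation-model
parameters, in the sample proportions, and (when applicable) in the
reference itself all surface in the between-imputation variance.

Two points in this recipe were genuinely open and are resolved as follows.

**The "refit with the offset fixed" step.** Refitting the imputation model
to the complete records with a fixed intercept offset is a no-op on the ML
estimates: an offset applied to the very records being fitted would be
absorbed into the free intercept, undoing the adjustment. The offset is
therefore applied only when predicting imputation probabilities for
nonrespondents, which is the pattern-mixture reading; step 5 redraws from
the unchanged $N(\hat\theta, \hat U)$. The test suite verifies that an
explicit zero-offset refit reproduces the complete-record coefficients
bit-for-bit.

**The variance denominator for $\tilde p_x$.** $\hat p_x$ is a
complete-record proportion, so its binomial variance uses the
complete-record count $n_{obs}$, not the total $n$. With ~45% missingness
the difference is a factor ~1.35 on the SE of one nuisance draw; the
choice slightly widens the δ spread across imputations and is the
conservative direction.

Other conventions: for $K>2$ the per-level nuisance and reference draws
are made independently and renormalised onto the simplex (only the binary
construction is canonical; renormalisation is the minimal symmetric
extension). Draws outside $(0,1)$ are rejected and redrawn — truncation
would bias the draw means, rejection does not at these sample sizes. The
multinomial base level defaults to the most frequent observed level (the
analogue of using the majority White group as base); for a binary
covariate the first declared level is kept so that coefficients match the
usual 2×2 closed forms.

## Numerical choices

* **Bisection**: initial bracket $[-30, 30]$, geometric expansion capped
  at $\pm 100$ (expit is flat beyond that at double precision), tolerance
  $10^{-10}$ on the proportion scale, 200-iteration cap. Monotonicity
  guarantees a unique root for any target in $(0,1)$.
* **Multinomial system**: damped Newton with the exact Jacobian
  $J_{jl} = \mathrm{mean}_i\, p_{ij}(1[j{=}l] - p_{il})$ (positive
  definite on the feasible set), step-halving on the residual max-norm;
  on the rare failure a cyclic per-coordinate bisection sweep — each
  margin is increasing in its own offset — takes over. Convergence
  declared at $10^{-10}$; hard failure beyond $10^{-8}$.
* **Degenerate inputs**: empty covariate cells, perfect separation,
  all-missing or no-missing data, degenerate external samples, and
  non-PSD parameter covariances all raise targeted errors rather than
  producing silently wrong numbers.

## Pooling

Rubin's rules per parameter: $\bar Q$, within-variance $W$ (mean squared
model SE), between-variance $B$, total $T = W + (1 + 1/M)B$. Degrees of
freedom default to the Barnard–Rubin small-sample rule (the default of
mainstream MI software, and what `df_complete` feeds); the classical
$(M-1)(1 + W/((1+1/M)B))^2$ is selectable. The fraction of missing
information defaults to $(B + B/M)/T$, with the df-adjusted variant
$(r + 2/(\nu+3))/(r+1)$ available — both are in circulation and the
source methodology does not commit to one. Relative efficiency is
$(1 + FMI/M)^{-1}$ and the Monte Carlo SE of the pooled estimate
$\sqrt{B/M}$.

## What the simulators emulate — and what they do not

`simulate_full_data()` reproduces the binary evaluation design:
$x \sim \mathrm{Bernoulli}(0.7)$,
$\mathrm{logit}\,p(y{=}1|x) = \ln 0.5 + \ln 1.5 \cdot x$, $n = 5000$.
`apply_selection()` implements the four selection mechanisms
(`default_selection_specs()`): M1 MCAR with $\alpha_0 = \ln(0.55/0.45)$
(45% missing by construction), M2 MAR-on-$y$ ($\alpha_y = 1.5$, response
OR $e^{1.5} \approx 4.5$, $\alpha_0 = -0.2$), M3 MNAR-on-$x$
($\alpha_x = -1.5$, $\alpha_0 = 1.35$), M4 MNAR-on-both
($\alpha_0 = 0.75$). The M2–M4 intercepts are the stated working values
for ≈45% missingness; only M1's rate is exact, so only M1's is asserted
numerically. External-reference designs draw an external sample of
$n^{ex}$ (10 000 "large", 1 000 "small") per repetition.

`simulate_casestudy_cohort()` mimics only the *structure* of an
electronic-health-records prevalence analysis: a 4-level covariate with a
dominant base level, independent categorical confounders (age group, sex,
deprivation quintile), a rare-ish binary outcome, MNAR selection on level
and outcome. Default level probabilities are census-like for an ethnically
diverse region (0.60/0.18/0.13/0.09); confounders are generated
independently because no joint distribution is part of the design —
dependence can be injected through the `outcome`/`selection` hooks.
Passing tests on these simulators shows the machinery is correct *under
the declared mechanisms*; it says nothing about real records, where
missingness may also depend on interactions or unmeasured factors and the
population reference may be misaligned with the sampled catchment.

## Problem sizes

The repeated-sampling checks in the test suite and acceptance script use
$S = 200$ repetitions with $M = 10$ imputations at $n = 5000$ — the
package's chosen desk-scale profile, large enough that Monte Carlo SEs
(≈0.005 on a bias, ≈1.5 points on a coverage) separate the methods
cleanly. The full-scale profile ($S = 2000$, $M = 50$) is one
`simulation_config()` call away and changes no code path.

## Known limitations

* One incomplete covariate only; no chained-equations embedding (though
  the univariate method could in principle serve as one conditional
  model inside MICE).
* The marginal calibration carries a single offset per level: a
  missingness mechanism involving an $x \times y$ interaction is not
  identified by marginal information and would need a second sensitivity
  parameter, as would a continuous outcome.
* Conditional (per-outcome-level) population distributions are not used
  even if available.
* The normal approximations for proportion draws are poor near 0 or 1 or
  in tiny samples; rejection sampling guards the support but not the
  shape.
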