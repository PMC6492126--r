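# calmi — population-calibrated δ-adjustment multiple imputation

`calmi` implements multiple imputation (MI) for a single incomplete binary
or categorical covariate in a categorical regression model when the data
may be **missing not at random (MNAR)** — the situation in which standard
MI, which assumes missingness at random (MAR), gives biased inference.

The motivating setting is routinely collected health data: ethnicity in UK
primary-care records is incompletely recorded, the probability of
recording plausibly depends on ethnic group itself, yet the *population*
distribution of ethnicity is known from the census. `calmi` feeds that
external information into the imputation model.

## The method

Let `x` be the incomplete covariate with response indicator `r` (1 =
observed), and `y` the fully observed binary outcome. The imputation model
fitted to the complete records is the (multinomial) logistic regression

```
logit p(x = 1 | y)  =  θ0 + θy y          (binary x)
```

Under a pattern-mixture view, the nonrespondents may differ from the
respondents by an intercept shift δ (an offset). By total probability, the
marginal distribution of `x` that the nonrespondents *must* carry to be
consistent with the population is

```
p(x=1 | r=0)  =  ( p_pop − p(x=1 | r=1) · p(r=1) ) / ( 1 − p(r=1) )
```

The **calibrated-δ adjustment** is the offset solving

```
(1/n_mis) Σ_i expit(θ0 + δ + θy y_i)  =  p(x=1 | r=0)
```

over the nonrespondents (interval bisection; the left side is strictly
increasing in δ). For a K-level covariate the same logic yields a system
of K−1 equations in the per-level offsets δ_j under the multinomial
softmax, solved by a damped Newton method with exact Jacobian. Each of the
M imputations re-solves δ from fresh posterior draws of the imputation
parameters and nuisance proportions (and, if the reference itself was
estimated in an external sample of size `n_ex`, a fresh draw of the
reference proportions), so all sources of uncertainty propagate into
Rubin's variance estimator. Setting δ ≡ 0 recovers standard MI exactly.

## Worked example

```r
library(calmi)
set.seed(42)
full <- simulate_full_data(5000)          # p(x=1)=0.7, beta0=ln(0.5), beta_x=ln(1.5)
obs  <- apply_selection(full, default_selection_specs()$M4)   # MNAR on x and y
mean(is.na(obs$x))                        # 0.442  -- ~44% missing
mean(complete_records(obs)$x == "1")      # 0.594  -- observed data underrepresent x=1

ref <- population_reference(c("0" = 0.3, "1" = 0.7))   # census-like reference
mi  <- multiply_impute(obs, x ~ y, method = "calibrated", M = 10, ref = ref)
mi
#> calibrated MI: M = 10 imputations of x (2209 missing of 5000)
#> mean delta adjustment: 1.507
mean(sapply(mi$imputations, function(d) mean(d$x == "1")))
#> 0.701                                  -- the population marginal is restored

pool_completed(mi, y ~ x)
#> Rubin's-rules pooled estimates (M = 10 imputations)
#>         term estimate      se     df conf_low conf_high    fmi     re    mcse
#>  (Intercept)  -0.6308 0.06445 104.79  -0.7586    -0.503 0.2887 0.9719 0.01044
#>           x1   0.3289 0.08243  57.05   0.1638     0.494 0.3934 0.9621 0.01559
```

The pooled intercept −0.63 and log odds ratio 0.33 are within sampling
error of the generating values ln(0.5) = −0.693 and ln(1.5) = 0.405,
while standard MI on the same data returns a clearly biased intercept of
−0.868. The `fmi` column is the fraction of missing information, `re` the
relative efficiency versus infinitely many imputations, `mcse` the Monte
Carlo standard error of the pooled estimate.

Repeated-sampling evaluation (bias, empirical and average model SE,
coverage, all with Monte Carlo SEs) is available through
`run_simulation_study(simulation_config(...))`, and a 4-level categorical
cohort with confounders for the multinomial path through
`simulate_casestudy_cohort()`. A thin command-line front end over these
functions lives in `inst/cli/calmi.R` (subcommands `generate`, `fixture`,
`impute`, `pool`, `simulate-study`).

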