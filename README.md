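# gompcr

Parametric competing-risks regression for dialysis cohorts, built around a
three-parameter (generalized) Gompertz sub-distribution with a plateau
(cure) mass.

## The problem

In end-stage renal disease cohorts, death on dialysis competes with kidney
transplantation: patients who receive a graft can no longer die on
dialysis, so treating transplants as plain censoring makes Kaplan–Meier
and Cox estimates biased.  `gompcr` models the cumulative incidence
(sub-distribution) of each cause directly and jointly.  It is aimed at
biostatisticians and nephrology researchers analysing registry-style data
with follow-up time, an event code (censored / death / transplant), and
clinical covariates.

## The model

Each cause *k* has the improper generalized Gompertz sub-distribution

    F_k(t | x) = [1 − exp(−(λ_k(x)/γ_k)(e^{γ_k t} − 1))]^{θ_k},
    λ_k(x) = λ_k exp(xᵀβ_k),

with power θ_k > 0, shape γ_k (per year) and rate λ_k > 0 (per year).
With γ_k < 0, F_k plateaus below 1; the plateau is the probability the
cause ever occurs, so two improper sub-distributions can share one cohort
(`F₁(∞|x) + F₂(∞|x) ≤ 1`).  The joint likelihood sums `log f₁` for deaths,
`log f₂` for transplants, and `log(1 − F₁ − F₂)` for censored records, and
is maximized by BFGS with a Newton polish on the transformed scale
(log θ, γ, log λ, β).  Covariate effects are reported as sub-hazard
ratios exp(β) with Wald intervals obtained by exponentiating the β
interval endpoints.

The package also ships

* a synthetic cohort generator (`simulate_cohort()`) whose packaged
  default (`default_cohort_config()`) is calibrated to a published
  hemodialysis cohort profile (n = 109; 26.6% deaths, 17.4% transplants
  observed; 4-year cumulative incidences 48.4% / 29.2%; 71.6% male; age
  57.99 ± 17.10), and
* a prognostic-factor screening pipeline (`run_screening()`): clinical
  lab categorization → univariate screen (p < 0.25, 75% CIs) →
  collinearity pruning → multivariate model (p < 0.10, 90% CIs) →
  cumulative incidence table.

## Worked example

```r
library(gompcr)

cfg    <- default_cohort_config(seed = 1)
cohort <- simulate_cohort(cfg)           # tibble: time, event, covariates
fit    <- crisk_fit(cohort, cause1 = ~ age + uric, cause2 = ~ age + uric)
fit
#> Gompertz competing-risks fit
#>   causes modeled: death, transplant
#>   n = 109 (events: 35 / 19), log-likelihood = -114.623
#>   converged: TRUE (|grad| = 4.24e-08)
#>   death: theta = 19.96, gamma = -0.8216, rate = 4.025, plateau = 0.8612
#>     S-HR: age = 1.004, uric = 0.931
#>   transplant: theta = 7.046, gamma = -1.433, rate = 1.999, plateau = 0.1344
#>     S-HR: age = 0.991, uric = 1.108

shr_table(fit)[, c("cause", "variable", "shr", "shr_ci_75", "shr_ci_90", "p.value")]
#> # A tibble: 4 × 6
#>   cause      variable   shr shr_ci_75        shr_ci_90        p.value
#>   <chr>      <chr>    <dbl> <chr>            <chr>              <dbl>
#> 1 death      age      1.00  1.00 (1.00-1.01) 1.00 (1.00-1.01)  0.239
#> 2 death      uric     0.931 0.93 (0.89-0.98) 0.93 (0.87-1.00)  0.103
#> 3 transplant age      0.991 0.99 (0.99-1.00) 0.99 (0.98-1.00)  0.0727
#> 4 transplant uric     1.11  1.11 (1.03-1.19) 1.11 (1.00-1.23)  0.0959

cif_curve(fit, newdata = data.frame(age = 58, uric = 7), times = 1:4)
#> # A tibble: 8 × 3
#>    time cause         cif
#>   <int> <chr>       <dbl>
#> 1     1 death      0.0634
#> 2     2 death      0.341
#> 3     3 death      0.488
#> 4     4 death      0.548
#> 5     1 transplant 0.113
#> 6     2 transplant 0.218
#> 7     3 transplant 0.247
#> 8     4 transplant 0.254
```

The S-HR column is the multiplicative effect of one unit of the covariate
on that cause's sub-distribution hazard (values above 1 hasten the
event): in this simulated cohort, each mg/dl of serum uric acid lowers
the sub-hazard of death by about 7% and raises that of transplantation by
about 11%, mirroring the directions the generator encodes.  `cif_curve()`
gives the model's cumulative incidence — the probability of having died
(resp. been transplanted) by each year for a 58-year-old female patient
with uric acid 7 mg/dl in the reference phosphorus band.  At one
simulated cohort of n = 109 the baseline shape parameters are imprecise
(the plateau estimates differ noticeably from the generating truth);
the sub-hazard ratios and the 4-year incidences are the stable,
reportable quantities.  `tidy(fit)`, `glance(fit)` and `autoplot(fit)`
give coefficient tables, fit summaries and CIF plots; `run_screening()`
drives the full univariate → multivariate workflow and writes TSV and
markdown reports.

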