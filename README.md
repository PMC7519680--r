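# transmr

Transient-aware capture–mark–recapture (CMR) models and their consequences
for local population dynamics.

## What it is for

In CMR studies of breeding animals, *transients* are individuals marked (or
first resighted) at their first breeding attempt and never encountered
again — they died or dispersed permanently right after it. Transients
depress the apparent survival of newly marked cohorts, show up as a
characteristic lack of fit of the Cormack–Jolly–Seber (CJS) model, and,
when first detections coincide with first breeding, measure a survival cost
of first reproduction with real population-level consequences.

`transmr` is for demographers and quantitative ecologists who want to run
that whole analysis chain in R:

* **Detect** transience: the directional goodness-of-fit test 3.SR, the
  companion memory test 3.Sm, and the overdispersion factor
  $\hat c = \sum\chi^2/\sum\mathrm{df}$ with per-component attribution.
* **Estimate** it: maximum-likelihood transient-CJS models on the m-array,
  with the transience probability $\tau$ estimated directly on a logit
  scale and structured by age-at-first-breeding group, time, or an
  environmental covariate (e.g. a food-per-capita density-dependence
  proxy): $\mathrm{logit}(\tau_{gt}) = \alpha_g + \beta x_t$. Model
  selection by AIC; analysis of deviance (ANODEV) to locate a covariate
  model between the constant and time-dependent ones.
* **Project** its consequences: a 17-stage pre-breeding-census matrix model
  of a long-lived seabird life cycle in which every recruit passes through
  a first-time-breeder stage with reduced fertility $F'$ and survival
  $\phi_A(1-\tau_i)$; asymptotic growth rate λ, stable structure,
  reproductive values, entry- and vital-rate-level sensitivities and
  elasticities; a fixed-design life table response experiment (LTRE)
  decomposing a λ difference between contrasting seasons into
  per-vital-rate contributions $\Delta p \cdot \partial\lambda/\partial p$;
  and a λ response surface over density × transience.
* **Simulate**: a generator of encounter histories with a latent truth
  record, plus `case_study_preset()` emulating a 25-year, five-age-group
  gull resighting study for calibration and recovery experiments.

Data I/O covers the MARK-style `.inp` dialect (with frequency columns per
group), long-format CSV histories, m-array CSV export, and vital-rate
tables as CSV/YAML. Everything returns tibbles and carries broom-style
`tidy()`/`glance()` methods and ggplot2 `autoplot()`s.

## A worked example

```r
library(transmr)

data <- simulate_histories(case_study_preset(), seed = 1)
test_3sr(data)
#> <GOF component 3.SR>
#>   chi-square = 1661.503 on 23 df, p = 0, directional z = 34.299

fit <- fit_transient_cjs(build_marray(data),
  cjs_spec(tau = ~ 0 + group + group:cov))
dplyr::group_by(tau_estimates(fit), group) |>
  dplyr::summarise(tau_min = min(tau), tau_max = max(tau))
#> # A tibble: 5 x 3
#>   group tau_min tau_max
#>   <fct>   <dbl>   <dbl>
#> 1 3     0.000212  0.0578
#> 2 4     0.00202   0.204
#> 3 5     0.199     0.441
#> 4 6     0.309     0.528
#> 5 7plus 0.349     0.831
```

The simulated study shows massive transience-type lack of fit (the positive
z is the transience direction), and the fitted model recovers the
generator's per-group transience ranges: near zero to ~0.2 for birds first
breeding at age 4, ~0.35 to ~0.83 for those recruiting after age 6 —
transience rises with age at first breeding and with density dependence.

```r
lt <- ltre_decompose(gull_vital_rates("good"), gull_vital_rates("bad"))
glance(lt)
#> # A tibble: 1 x 5
#>   lambda_good lambda_bad lambda_delta sum_of_contributions residual
#> 1        1.09      0.944       -0.144               -0.145  0.00118
```

Between the two published season parameterizations the population flips
from growth (λ ≈ 1.088) to decline (λ ≈ 0.944); the LTRE attributes the
change mostly to adult survival (−0.061) and resident fertility (−0.044),
with the per-parameter table (`tidy(lt)`) carrying the per-age transience
and recruitment terms, their aggregates, and both sensitivity conventions.
`autoplot(lambda_surface())` draws the λ surface over density × τ₄.

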