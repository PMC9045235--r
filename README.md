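# attribwork

Comparative risk assessment (CRA) of occupational exposures in R: the
burden of a health outcome attributable to a workplace risk factor is
the population attributable fraction (PAF) applied to the outcome's
total deaths/DALY envelope. The package is aimed at burden-of-disease
modellers who need the full estimation chain — exposure modelling,
attribution, inequality metrics and uncertainty — as tested, seeded,
reusable functions rather than one-off scripts.

## What it computes

For a risk–outcome pair with exposure prevalence *P* and pooled
relative risk RR (e.g. working ≥55 h/week and stroke, RR 1.35, 95% CI
1.13–1.61), the PAF is Levin's single-exposed-category form

    PAF = P(RR − 1) / (P(RR − 1) + 1)

and attributable burden = PAF × envelope. Pairs whose PAF comes from an
external burden study use that fraction directly ("transfer" pairs).
Around this core the package provides:

* `fit_prevalence_model()` — hierarchical exposure-prevalence model on
  the logit scale (global intercept + region and country random effects
  + year trend), fitted to survey data weighted by sample size; a
  classed fit with `predict`/`summary`/`coef`/`residuals`/`plot`/
  `simulate` methods.
* `lag_window()`, `windowed_prevalence()` — lagged exposure windows
  (default 10-year window at a 10-year lag: burden year 2016 uses
  exposure 2001–2010).
* `levin_paf()`, `transfer_paf()`, `attributable_burden()`,
  `aggregate_burden()`, `top_pair()` — attribution and aggregation.
* `rate_per_100k()`, `rate_difference()`, `rate_ratio()`,
  `trend_change()`, `inequality_records()` — per-100 000 working-age
  rates and inequality/trend metrics.
* `rr_draws()`, `prevalence_draws()`, `propagate_burden()`,
  `summarize_ur()` — seeded bootstrap 95% uncertainty ranges (URs).
* `simulate_scenario()` — synthetic survey/envelope/population bundles
  with known ground truth; `run_pipeline()` — end-to-end orchestration;
  `load_table1()` — packaged, checksum-verified table of published
  global estimates for 41 risk–outcome pairs.

A thin CLI over these functions ships in `inst/cli/attribwork.R`
(subcommands `simulate`, `fit-exposure`, `run`, `fixture-check`).

## Worked example

```r
library(attribwork)

# Published global estimates, 41 pairs
long <- table1_long(load_table1())
subset(aggregate_burden(long, by = c("measure", "year")), year == 2016)
#>   measure year    value
#> 3    daly 2016 89716657
#> 6  deaths 2016  1879890
top_pair(long, "deaths", 2016)
#> $pair_id
#> [1] "particulates_copd"
#> $value
#> [1] 450381
```

1 879 890 deaths and 89.7 million DALY were attributable to the 41
pairs in 2016; the single largest death toll is chronic obstructive
pulmonary disease from occupational particulates (450 381 deaths).

```r
# Synthetic scenario with known truth, end to end
sc  <- simulate_scenario(scenario_config(seed = 42))
fit <- fit_prevalence_model(sc$inputs$surveys, sc$inputs$hierarchy)
fit
#> Hierarchical exposure-prevalence model (logit scale)
#>   150 surveys, 15 countries, 3 regions; years 1985-2016
#>   intercept -1.8006 (prevalence 0.1418 at year 2000.5), trend -0.00960/yr
#>   SD(region) 0.279  SD(country) 0.359  residual SD 2.927

res <- run_pipeline(sc$inputs, burden_years = 2016, n_draws = 200, seed = 42)
res$global_ur
#>   measure year     value   ur_lower  ur_upper
#> 1    daly 2016 3068308.8 2557068.12 3653887.6
#> 2  deaths 2016  105989.7   89207.86  125235.3
true_burden(sc$truth, by = c("measure", "year"))
#>   measure year     value
#> 1    daly 2016 3061342.8
#> 2  deaths 2016  105760.3
```

The estimated global attributable burden (105 990 deaths, 95% UR
89 208–125 235) brackets the scenario's true value (105 760): the
pipeline recovers the ground truth it was pointed at, with the UR
reflecting survey and relative-risk uncertainty.

## Package layout

The methods — model form, window convention, bootstrap design,
generator defaults and known limitations — are documented in
`vignettes/attributable-burden.Rmd`.
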