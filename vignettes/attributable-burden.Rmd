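---
title: "Estimating work-related burden of disease with attribwork"
author: "attribwork maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating work-related burden of disease with attribwork}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(attribwork)
```

## The estimation problem

Global estimates of work-related burden of disease are built within the
comparative risk assessment (CRA) framework: for each pair of an
occupational risk factor and a health outcome, the fraction of the
outcome's total burden attributable to the exposure — the population
attributable fraction (PAF) — is applied to the outcome's total deaths
and disability-adjusted life years (DALY), the *envelopes*. attribwork
implements this chain for two families of pairs:

* **Transfer pairs**: the PAF is taken from an external burden study and
  applied directly (`transfer_paf()` for deriving a fraction from
  attributable/total counts, or a supplied PAF table).
* **Prevalence/relative-risk pairs**: the PAF is computed with Levin's
  single-exposed-category formula,
  $$\mathrm{PAF} = \frac{P\,(\mathrm{RR}-1)}{P\,(\mathrm{RR}-1)+1},$$
  from the modelled prevalence of exposure $P$ and a pooled relative
  risk RR from meta-analysis. The motivating application is exposure to
  long working hours (working $\ge$ 55 hours per week), with pooled RRs
  of 1.17 (95% CI 1.05–1.31) for ischemic heart disease and 1.35
  (95% CI 1.13–1.61) for stroke.

## The exposure model

Survey estimates of exposure prevalence (mostly labour-force surveys)
are sparse and noisy, so country-year prevalence is predicted from a
hierarchical model fitted on the logit scale:

$$\mathrm{logit}(p_{ct}) = \beta_0 + u_{r(c)} + u_c + \beta_1 (t - t_0),$$

with independent normal random intercepts for region ($u_r$) and country
($u_c$) and a global linear year trend. `fit_prevalence_model()` fits
this as a weighted linear mixed model (`lme4::lmer`), weighting each
survey by its sample size; country and region effects are the
empirical-Bayes (BLUP) estimates. This is a deliberately minimal
multilevel structure: it is the smallest model that pools strength
across the hierarchy while remaining estimable from a handful of surveys
per country, and it is stated explicitly so that recovery tests against
synthetic data are well defined.

Numerical choices worth knowing:

* Observed prevalences of exactly 0 or 1 are clamped to
  $[1/(4n_s),\, 1 - 1/(4n_s)]$ before the logit (a standard continuity
  correction; $n_s$ is the survey sample size).
* The trend's reference year $t_0$ is the midpoint of the observed year
  range, for numerical conditioning.
* With a single region the region term is dropped; with a single country
  (or zero-variance data, where mixed-model optimisation is
  ill-defined) the fit degrades to weighted least squares and the
  random-effect variances are reported as 0.
* Cell-level prediction standard errors use the *joint* conditional
  covariance of the random effects,
  $\mathrm{Var}(b \mid y) = \sigma^2 \Lambda (\Lambda' Z' W Z \Lambda +
  I)^{-1} \Lambda'$, not the per-term conditional variances: country and
  region BLUP errors are strongly anti-correlated with the intercept's
  sampling error, and ignoring that correlation overstates cell
  uncertainty by an order of magnitude. The full fixed-effect
  covariance enters only for countries predicted without any surveys.
* Predictions outside the observed year range extrapolate linearly on
  the logit scale and carry an `extrapolated` flag.

## The lagged exposure window

Chronic outcomes respond to past, not current, exposure. Burden in year
$Y$ is therefore attributed using the mean prevalence over a block of
`width` consecutive years centred on $Y - \mathrm{lag}$
(`lag_window()`, `window_years()`, `windowed_prevalence()`). The
defaults — a 10-year window around a 10-year lag — map burden year 2016
to exposure years 2001–2010. Sensitivity analyses that alter the lag or
width re-select years from the same fitted surface; they never change
the fit itself.

```{r window}
window_years(2016, lag_window(lag = 10, width = 10))
```

## Uncertainty

95% uncertainty ranges (UR) are produced by seeded bootstrap
(`rr_draws()`, `prevalence_draws()`, `propagate_burden()`,
`summarize_ur()`):

* RR draws are lognormal with median at the published point estimate and
  $\sigma_{\log} = (\log \mathrm{CI}_{hi} - \log \mathrm{CI}_{lo}) /
  (2 \times 1.959964)$ — the standard parameterisation of a ratio
  measure from its CI.
* Prevalence draws are normal on the logit scale around the predicted
  surface with its cell standard error, back-transformed (so draws stay
  in $(0,1)$).
* RR and prevalence are drawn independently; the i-th prevalence draw is
  paired with the i-th RR draw, the Levin PAF evaluated per draw, and
  multiplied by the fixed envelope. Envelope uncertainty is *not*
  propagated — only exposure and risk uncertainty enter the UR.
* The UR limits are the empirical 2.5% and 97.5% quantiles
  (linear-interpolation definition, R's `type = 7`), pinned for
  reproducibility. The reported point estimate is the computation at
  point inputs, not the draw mean.
* Every random step takes an explicit integer seed; with a fixed seed
  the whole pipeline is byte-reproducible (wall-clock defaults are
  deliberately not allowed).

## Inequality and trend metrics

`rate_per_100k()` converts counts to rates per 100 000 working-age
(aged $\ge$ 15) population. Inequalities along one dimension (sex, age
group or region — regions in the motivating application are the six WHO
regions AFR, AMR, SEA, EUR, EMR, WPR) are summarised by the rate
difference (group minus reference, absolute inequality) and the rate
ratio (group over reference, relative inequality), with the global
working-age rate as the reference (`inequality_records()`). Reported
rates and ratios are rounded half-up to one decimal
(`round_half_up()`); all computation is at full precision and rounding
happens only at the reporting edge. Age bands run "15–19" … "85–89"
plus "90+", so the oldest reported band is never an open-ended 85+.
Crude working-age rates are used throughout — no age standardisation.

## Synthetic data and what the tests show

`simulate_scenario()` generates an internally consistent bundle —
surveys, hierarchy, envelopes, populations, transfer PAFs — plus the
ground truth behind it (true surface, true windowed prevalence, true
PAFs via the Levin formula, true attributable burden). The generator's
defaults are fixed study conditions, not tuning knobs:

* 3 regions × 5 countries, years 1985–2016 — a desk-scale analogue of a
  multi-country survey database, runnable in seconds;
* global logit prevalence $-2$ ($\approx$ 12%, the order of the global
  prevalence of working $\ge$ 55 h/week), region and country SD 0.3 on
  the logit scale, a mild declining trend ($-0.01$/year);
* binomial survey noise at $n_s = 2000$, 10 surveys per country —
  labour-force surveys report design-based proportions, and binomial
  sampling is the minimal faithful noise model;
* gamma-distributed envelopes (mean 1000 deaths, 30 000 DALY per
  stratum) and lognormal stratum populations;
* exposure prevalence is generated at country-year level and shared
  across sex/age strata; published sources do not pin down the sex/age
  disaggregation of exposure, so the simplest defensible default is
  used.

The suite demonstrates parameter recovery (mean absolute error of the
predicted surface below 0.02 under 30 surveys/country), calibrated
prediction intervals (coverage within 90–99%), and end-to-end recovery
of true global attributable deaths inside the bootstrap UR in at least
90% of 100 replicates (200 draws each; problem sizes chosen so the
full suite runs in well under a minute). What these tests do *not*
show: robustness to survey design effects, non-response or
instrument-mix heterogeneity, to exposure trends that are non-linear on
the logit scale, or to envelope mis-specification — real survey
databases have all of these, and the generator deliberately does not.

## The packaged estimates fixture

`load_table1()` returns a transcription of published global estimates
for 41 risk-outcome pairs (attributable deaths and DALY with per-100 000
working-age rates for 2000, 2010 and 2016), checksum-verified on load.
It exercises the aggregation, trend and arg-max machinery against known
totals:

```{r table1}
t1 <- load_table1()
long <- table1_long(t1)
tot <- aggregate_burden(long, by = c("measure", "year"))
subset(tot, year == 2016)
top_pair(long, "deaths", 2016)
```

Two reporting quirks are handled deliberately: non-fatal outcomes
(hearing loss, back/neck pain) legitimately carry zero deaths and must
not error; and the published percent decline in the global death rate is
derived from unrounded totals, so it is not reproducible from the
rounded printed rates — the package reports what it computes and does
not chase that figure.

## A worked run

```{r pipeline}
sc <- simulate_scenario(scenario_config(seed = 42))
res <- run_pipeline(sc$inputs, burden_years = 2016, n_draws = 200,
                    seed = 42)
res$global_ur
truth <- true_burden(sc$truth, by = c("measure", "year"))
truth
```

The true global burden falls inside the bootstrap UR; the point
estimate differs from truth only through survey noise in the fitted
exposure surface (transfer-pair inputs are exact in this scenario).

## Known limitations

* The hierarchical model is a stated stand-in for the (unpublished)
  production exposure model; it is validated by recovery on synthetic
  data only.
* One PAF per (pair, country, year) is applied uniformly across sex/age
  unless a finer PAF table is supplied.
* Summation across pairs ignores co-attribution (one death can be
  attributable to several risk factors); totals follow the plain-sum
  reporting convention.
* Draws are independent across countries beyond what shared fixed
  effects induce; RR and prevalence draws are independent of each
  other.
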