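# Shared fixture builders (all generated in code, no files)

# minimal deterministic scenario used by several suites
tiny_scenario <- function(seed = 11, ...) {
  simulate_scenario(scenario_config(
    n_regions = 2, countries_per_region = 3, years = 1995:2016,
    surveys_per_country = 8, seed = seed, ...
  ))
}

# constant exposure surface over a year span for one country
flat_surface <- function(p = 0.2, years = 1990:2016, iso3 = "AAA",
                         se_logit = 0) {
  data.frame(iso3 = iso3, year = years, prevalence = p,
             se_logit = se_logit, stringsAsFactors = FALSE)
}

# one-cell envelope table
one_cell_envelope <- function(cause, value, measure = "deaths",
                              iso3 = "AAA", year = 2016, sex = "male",
                              age_group = "40-44") {
  data.frame(cause = cause, iso3 = iso3, year = year, sex = sex,
             age_group = age_group, measure = measure, value = value,
             stringsAsFactors = FALSE)
}

# cohort simulation oracle for the Levin PAF: a closed cohort of size n
# with exposure prevalence p_exp, baseline risk p0, exposed risk p0*rr.
# Returns the empirical PAF and its Monte-Carlo standard error.
cohort_paf <- function(p_exp, rr, n = 1e6, p0 = 0.05) {
  n_exp <- rbinom(1, n, p_exp)
  cases <- rbinom(1, n_exp, p0 * rr) + rbinom(1, n - n_exp, p0)
  counterfactual <- rbinom(1, n, p0)
  paf <- (cases - counterfactual) / cases
  pf <- p0 * (1 + p_exp * (rr - 1))
  se <- (p0 / pf) * sqrt((1 - p0) / (n * p0) + (1 - pf) / (n * pf))
  list(paf = paf, se = se)
}
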