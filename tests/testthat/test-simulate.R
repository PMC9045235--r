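test_that("zero variance and zero trend give a flat surface at logit^-1(0)", {
  sc <- simulate_scenario(scenario_config(
    region_sd = 0, country_sd = 0, annual_trend = 0,
    true_global_logit_prevalence = 0, seed = 1
  ))
  expect_equal(unique(sc$truth$surface$prevalence), 0.5)
})

test_that("invalid configurations are rejected naming the field", {
  expect_error(scenario_config(region_sd = -1), "region_sd")
  expect_error(scenario_config(country_sd = -0.1), "country_sd")
  expect_error(scenario_config(years = integer(0)), "years")
  expect_error(scenario_config(burden_years = 1900), "burden_years")
})

test_that("huge survey samples pin observed prevalence to the truth", {
  sc <- simulate_scenario(scenario_config(survey_sample_size = 1e6,
                                          seed = 5))
  truth <- sc$truth$surface
  obs <- sc$inputs$surveys
  p_true <- truth$prevalence[match(paste(obs$iso3, obs$year),
                                   paste(truth$iso3, truth$year))]
  expect_lt(mean(abs(obs$prevalence - p_true)), 0.002)
})

test_that("country-year survey means converge to the true prevalence", {
  sc <- simulate_scenario(scenario_config(
    surveys_per_country = 20, survey_sample_size = 1e5, seed = 9
  ))
  obs <- sc$inputs$surveys
  truth <- sc$truth$surface
  cell_mean <- aggregate(prevalence ~ iso3 + year, obs, mean)
  p_true <- truth$prevalence[match(paste(cell_mean$iso3, cell_mean$year),
                                   paste(truth$iso3, truth$year))]
  expect_true(all(obs$prevalence >= 0 & obs$prevalence <= 1))
  expect_true(all(abs(cell_mean$prevalence - p_true) < 0.01))
})

test_that("identical seed and config reproduce the bundle byte for byte", {
  cfg <- scenario_config(seed = 42)
  d1 <- file.path(tempdir(), "bundle_a")
  d2 <- file.path(tempdir(), "bundle_b")
  write_scenario(simulate_scenario(cfg), d1)
  write_scenario(simulate_scenario(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     label = sprintf("file %s run 1", f))
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("true burden is additive and bounded by the envelopes", {
  sc <- tiny_scenario()
  per_stratum <- sc$truth$burden
  global <- true_burden(sc$truth, by = c("pair_id", "measure"))
  by_hand <- tapply(per_stratum$value,
                    paste(per_stratum$pair_id, per_stratum$measure), sum)
  expect_equal(global$value,
               as.numeric(by_hand[paste(global$pair_id, global$measure)]))
  env <- sc$inputs$envelopes
  pairs <- sc$inputs$pairs
  env_val <- env$value[match(
    paste(pairs$outcome[match(per_stratum$pair_id, pairs$pair_id)],
          per_stratum$iso3, per_stratum$year, per_stratum$sex,
          per_stratum$age_group, per_stratum$measure),
    paste(env$cause, env$iso3, env$year, env$sex, env$age_group,
          env$measure))]
  expect_true(all(per_stratum$value <= env_val + 1e-9))
  expect_error(true_burden(sc$truth, by = "no_such_key"), "grouping")
})

test_that("a null relative risk produces zero attributable burden", {
  pairs <- default_pairs()[1:2, ]  # levin pairs only
  sc <- simulate_scenario(scenario_config(
    pairs = pairs, true_rr = c(long_hours_ihd = 1, long_hours_stroke = 1),
    seed = 3
  ))
  expect_true(all(sc$truth$paf$paf == 0))
  expect_true(all(sc$truth$burden$value == 0))
})

test_that("a 2-country, 1-pair scenario matches hand-computed Levin truth", {
  pairs <- default_pairs()[2, ]  # stroke pair, RR 1.35
  sc <- simulate_scenario(scenario_config(
    n_regions = 1, countries_per_region = 2, pairs = pairs, seed = 8
  ))
  w <- sc$truth$windowed
  for (cc in w$iso3) {
    P <- w$prevalence[w$iso3 == cc]
    paf_hand <- P * 0.35 / (P * 0.35 + 1)
    strata <- sc$truth$burden[sc$truth$burden$iso3 == cc, ]
    env <- sc$inputs$envelopes
    env_v <- env$value[match(
      paste("Stroke", strata$iso3, strata$year, strata$sex,
            strata$age_group, strata$measure),
      paste(env$cause, env$iso3, env$year, env$sex, env$age_group,
            env$measure))]
    expect_equal(strata$value, paf_hand * env_v, tolerance = 1e-12)
  }
})
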