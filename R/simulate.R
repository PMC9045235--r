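#' Configure a synthetic burden-attribution scenario
#'
#' Builds and validates the configuration for [simulate_scenario()]. The
#' generator emulates, at desk scale, the kind of inputs a global
#' occupational-burden study consumes: multi-country labour-force-survey
#' estimates of the prevalence of working long hours (>= 55 h/week), total
#' deaths/DALY envelopes, population tables, and externally supplied
#' transfer PAFs — together with the ground truth behind them.
#'
#' True prevalence is built on the logit scale as
#' `global + region effect + country effect + trend * (year - mid-year)`,
#' with region and country effects drawn from centred normal distributions.
#' Surveys observe a binomial proportion: `rbinom(n_s, p)/n_s`.
#'
#' @param n_regions number of regions.
#' @param countries_per_region countries within each region.
#' @param years inclusive calendar-year range covered by the true surface.
#' @param age_groups ordered age-band labels (default 5-year bands
#'   "15-19" ... "85-89" plus "90+").
#' @param sexes sex labels.
#' @param true_global_logit_prevalence global intercept on the logit scale.
#'   The default -2 corresponds to ~12% exposure prevalence.
#' @param region_sd,country_sd standard deviations of region and country
#'   effects (logit scale); must be >= 0.
#' @param annual_trend linear trend per year on the logit scale.
#' @param surveys_per_country number of surveys generated per country.
#' @param survey_sample_size binomial sample size n_s per survey.
#' @param pairs data.frame registry of risk-outcome pairs with columns
#'   pair_id, risk_factor, outcome, paf_mode ("levin" or "transfer"),
#'   rr_point, rr_lo, rr_hi (NA for transfer pairs), measures
#'   (comma-separated subset of "deaths,daly"). The default holds the two
#'   long-working-hours pairs (ischemic heart disease RR 1.17, stroke
#'   RR 1.35) plus one transfer pair.
#' @param true_rr named vector of true relative risks for levin pairs used
#'   to build the ground-truth PAFs (defaults to the registry's rr_point).
#' @param envelope_scale mean envelope count per stratum (deaths; DALY
#'   envelopes are scaled up 30-fold).
#' @param burden_years years for which envelopes, populations, PAFs and
#'   truth are produced.
#' @param window [lag_window()] used to define the ground-truth windowed
#'   prevalence feeding the true PAFs.
#' @param seed integer seed; identical config + seed reproduces the bundle
#'   byte-for-byte.
#' @return a validated list of class `scenario_config`.
#' @seealso [simulate_scenario()]
#' @export
scenario_config <- function(n_regions = 3,
                            countries_per_region = 5,
                            years = 1985:2016,
                            age_groups = default_age_groups(),
                            sexes = c("male", "female"),
                            true_global_logit_prevalence = -2,
                            region_sd = 0.3,
                            country_sd = 0.3,
                            annual_trend = -0.01,
                            surveys_per_country = 10,
                            survey_sample_size = 2000,
                            pairs = default_pairs(),
                            true_rr = NULL,
                            envelope_scale = 1000,
                            burden_years = 2016,
                            window = lag_window(),
                            seed = 1L) {
  cfg <- list(
    n_regions = n_regions, countries_per_region = countries_per_region,
    years = years, age_groups = age_groups, sexes = sexes,
    true_global_logit_prevalence = true_global_logit_prevalence,
    region_sd = region_sd, country_sd = country_sd,
    annual_trend = annual_trend,
    surveys_per_country = surveys_per_country,
    survey_sample_size = survey_sample_size,
    pairs = pairs, true_rr = true_rr,
    envelope_scale = envelope_scale,
    burden_years = burden_years, window = window, seed = seed
  )
  if (n_regions < 1) stop_field("n_regions", "must be >= 1")
  if (countries_per_region < 1) stop_field("countries_per_region", "must be >= 1")
  if (length(years) < 1) stop_field("years", "empty year range")
  if (region_sd < 0) stop_field("region_sd", "must be >= 0")
  if (country_sd < 0) stop_field("country_sd", "must be >= 0")
  if (surveys_per_country < 1) stop_field("surveys_per_country", "must be >= 1")
  if (survey_sample_size < 1) stop_field("survey_sample_size", "must be >= 1")
  if (envelope_scale <= 0) stop_field("envelope_scale", "must be > 0")
  if (!all(burden_years %in% years)) {
    stop_field("burden_years", "must lie within `years`")
  }
  check_columns(pairs, c("pair_id", "risk_factor", "outcome", "paf_mode",
                         "rr_point", "rr_lo", "rr_hi", "measures"), "pairs")
  if (!all(pairs$paf_mode %in% c("levin", "transfer"))) {
    stop_field("pairs", "paf_mode must be 'levin' or 'transfer'")
  }
  lev <- pairs$paf_mode == "levin"
  if (any(lev) && any(is.na(pairs$rr_point[lev]) | pairs$rr_point[lev] <= 0)) {
    stop_field("pairs", "levin pairs need rr_point > 0")
  }
  if (is.null(cfg$true_rr)) {
    cfg$true_rr <- setNames(pairs$rr_point[lev], pairs$pair_id[lev])
  }
  structure(cfg, class = "scenario_config")
}

#' Default working-age 5-year age bands
#'
#' "15-19" through "85-89" plus a terminal "90+".
#' @return character vector of labels.
#' @export
default_age_groups <- function() {
  c(paste(seq(15, 85, 5), seq(19, 89, 5), sep = "-"), "90+")
}

#' Default risk-outcome pair registry for simulations
#'
#' Two prevalence/relative-risk ("levin") pairs mirroring the long-working-
#' hours evidence base (ischemic heart disease, pooled RR 1.17, 95% CI
#' 1.05-1.31; stroke, pooled RR 1.35, 95% CI 1.13-1.61) and one pair whose
#' PAF is transferred from an external burden study.
#' @return data.frame registry.
#' @export
default_pairs <- function() {
  data.frame(
    pair_id = c("long_hours_ihd", "long_hours_stroke", "particulates_copd"),
    risk_factor = c("Exposure to long working hours",
                    "Exposure to long working hours",
                    "Occupational particulate matter, gases and fumes"),
    outcome = c("Ischemic heart disease", "Stroke",
                "Chronic obstructive pulmonary disease"),
    paf_mode = c("levin", "levin", "transfer"),
    rr_point = c(1.17, 1.35, NA),
    rr_lo = c(1.05, 1.13, NA),
    rr_hi = c(1.31, 1.61, NA),
    measures = "deaths,daly",
    stringsAsFactors = FALSE
  )
}

# deterministic 3-letter country codes: AAA, AAB, ...
country_codes <- function(n) {
  stopifnot(n <= 26^2)
  paste0("A", LETTERS[(seq_len(n) - 1) %/% 26 + 1],
         LETTERS[(seq_len(n) - 1) %% 26 + 1])
}

#' Generate a synthetic input bundle with known ground truth
#'
#' Draws region/country effects, builds the true prevalence surface,
#' samples binomial surveys around it, generates envelopes, populations
#' and a transfer-PAF table, and computes the true PAFs (Levin formula on
#' the true windowed prevalence) and true attributable burden per stratum.
#'
#' @param config a [scenario_config()].
#' @return list with elements
#'   \describe{
#'     \item{inputs}{list of data.frames: `surveys`, `hierarchy`,
#'       `envelopes`, `population`, `transfer_paf`, `pairs`}
#'     \item{truth}{list of class `scenario_truth`: `surface` (iso3, year,
#'       prevalence), `windowed` (iso3, burden year, windowed prevalence),
#'       `paf` (pair_id, iso3, year, paf), `burden` (per-stratum true
#'       attributable burden)}
#'     \item{config}{the config used}
#'   }
#' @examples
#' sc <- simulate_scenario(scenario_config(seed = 42))
#' head(sc$inputs$surveys)
#' @export
simulate_scenario <- function(config) {
  if (!inherits(config, "scenario_config")) {
    stop("`config` must come from scenario_config()", call. = FALSE)
  }
  with_seed(config$seed, simulate_scenario_impl(config))
}

simulate_scenario_impl <- function(cfg) {
  n_c <- cfg$n_regions * cfg$countries_per_region
  iso3 <- country_codes(n_c)
  region <- paste0("R", rep(seq_len(cfg$n_regions), each = cfg$countries_per_region))
  hierarchy <- data.frame(iso3 = iso3, region = region, stringsAsFactors = FALSE)

  u_region <- rnorm(cfg$n_regions, 0, cfg$region_sd)
  u_country <- rnorm(n_c, 0, cfg$country_sd)
  mid_year <- mean(range(cfg$years))

  surface <- expand.grid(iso3 = iso3, year = cfg$years,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  idx <- match(surface$iso3, iso3)
  eta <- cfg$true_global_logit_prevalence +
    u_region[(idx - 1) %/% cfg$countries_per_region + 1] +
    u_country[idx] +
    cfg$annual_trend * (surface$year - mid_year)
  surface$prevalence <- plogis(eta)
  surface <- surface[order(surface$iso3, surface$year), , drop = FALSE]
  rownames(surface) <- NULL

  # binomial surveys around the true country-year prevalence
  svy_year <- unlist(lapply(seq_len(n_c), function(i) {
    sort(sample(cfg$years, cfg$surveys_per_country, replace = TRUE))
  }))
  surveys <- data.frame(
    iso3 = rep(iso3, each = cfg$surveys_per_country),
    year = svy_year, stringsAsFactors = FALSE
  )
  p_true <- surface$prevalence[match(paste(surveys$iso3, surveys$year),
                                     paste(surface$iso3, surface$year))]
  surveys$prevalence <- rbinom(nrow(surveys), cfg$survey_sample_size, p_true) /
    cfg$survey_sample_size
  surveys$sample_size <- cfg$survey_sample_size

  causes <- unique(cfg$pairs$outcome)
  strata <- expand.grid(iso3 = iso3, year = cfg$burden_years, sex = cfg$sexes,
                        age_group = cfg$age_groups,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  env_one <- function(cause, measure, scale) {
    out <- strata
    out$cause <- cause
    out$measure <- measure
    out$value <- rgamma(nrow(strata), shape = 4, scale = scale / 4)
    out[c("cause", "iso3", "year", "sex", "age_group", "measure", "value")]
  }
  envelopes <- do.call(rbind, c(
    lapply(causes, env_one, measure = "deaths", scale = cfg$envelope_scale),
    lapply(causes, env_one, measure = "daly", scale = cfg$envelope_scale * 30)
  ))
  rownames(envelopes) <- NULL

  population <- strata
  population$pop <- round(exp(rnorm(nrow(strata), log(5e5), 0.3)))

  # true windowed prevalence per country x burden year (Levin inputs)
  windowed <- do.call(rbind, lapply(cfg$burden_years, function(by) {
    yrs <- window_years(by, cfg$window)
    sub <- surface[surface$year %in% yrs, , drop = FALSE]
    agg <- aggregate(prevalence ~ iso3, sub, mean)
    data.frame(iso3 = agg$iso3, year = by, prevalence = agg$prevalence,
               stringsAsFactors = FALSE)
  }))

  lev <- cfg$pairs[cfg$pairs$paf_mode == "levin", , drop = FALSE]
  paf_levin <- do.call(rbind, lapply(seq_len(nrow(lev)), function(i) {
    data.frame(pair_id = lev$pair_id[i], iso3 = windowed$iso3,
               year = windowed$year,
               paf = levin_paf(windowed$prevalence,
                               cfg$true_rr[[lev$pair_id[i]]]),
               stringsAsFactors = FALSE)
  }))

  tra <- cfg$pairs[cfg$pairs$paf_mode == "transfer", , drop = FALSE]
  transfer <- do.call(rbind, lapply(tra$pair_id, function(pid) {
    grid <- expand.grid(iso3 = iso3, year = cfg$burden_years,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    grid$pair_id <- pid
    grid$paf <- runif(nrow(grid), 0.05, 0.25)
    grid[c("pair_id", "iso3", "year", "paf")]
  }))
  if (is.null(transfer)) {
    transfer <- data.frame(pair_id = character(), iso3 = character(),
                           year = integer(), paf = double())
  }

  paf_all <- rbind(paf_levin, transfer)
  burden <- attributable_burden(paf_all, envelopes, cfg$pairs)

  truth <- structure(list(surface = surface, windowed = windowed,
                          paf = paf_all, burden = burden),
                     class = "scenario_truth")
  list(inputs = list(surveys = surveys, hierarchy = hierarchy,
                     envelopes = envelopes, population = population,
                     transfer_paf = transfer, pairs = cfg$pairs),
       truth = truth, config = cfg)
}

#' Aggregate ground-truth attributable burden
#'
#' Sums the scenario's true attributable burden to a requested grouping;
#' the recovery target for end-to-end tests.
#'
#' @param truth the `truth` element of [simulate_scenario()] output.
#' @param by character vector of grouping keys among
#'   pair_id, iso3, year, sex, age_group, measure.
#' @return aggregated data.frame with a `value` column.
#' @export
true_burden <- function(truth, by = c("pair_id", "measure")) {
  if (!inherits(truth, "scenario_truth")) {
    stop("`truth` must come from simulate_scenario()", call. = FALSE)
  }
  aggregate_burden(truth$burden, by = by)
}

#' Write a simulated bundle as tidy CSV files
#'
#' Writes `surveys.csv`, `hierarchy.csv`, `envelopes.csv`,
#' `population.csv`, `transfer_paf.csv`, `pairs.csv` and
#' `truth_surface.csv`, `truth_paf.csv`, `truth_burden.csv` under `dir`.
#'
#' @param scenario output of [simulate_scenario()].
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of file paths written.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tabs <- c(scenario$inputs,
            list(truth_surface = scenario$truth$surface,
                 truth_paf = scenario$truth$paf,
                 truth_burden = scenario$truth$burden))
  names(tabs)[names(tabs) == "transfer_paf"] <- "transfer_paf"
  paths <- vapply(names(tabs), function(nm) {
    p <- file.path(dir, paste0(nm, ".csv"))
    write_table(tabs[[nm]], p)
    p
  }, character(1))
  invisible(paths)
}
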