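#' Burden rate per 100 000 population
#'
#' @param count burden count (deaths or DALY), >= 0.
#' @param population denominator population, > 0 (typically working-age,
#'   i.e. aged >= 15).
#' @return rate per 100 000 (vectorised).
#' @examples
#' rate_per_100k(343, 1e6)  # 34.3
#' @export
rate_per_100k <- function(count, population) {
  if (any(population <= 0)) stop("`population` must be > 0", call. = FALSE)
  1e5 * count / population
}

#' Rate difference (absolute inequality)
#'
#' Group rate minus reference rate.
#' @param group_rate,reference_rate per-100 000 rates.
#' @return signed difference.
#' @examples
#' rate_difference(51.4, 34.3)  # 17.1
#' @export
rate_difference <- function(group_rate, reference_rate) {
  group_rate - reference_rate
}

#' Rate ratio (relative inequality)
#'
#' Group rate divided by reference rate.
#' @param group_rate,reference_rate per-100 000 rates; reference > 0.
#' @return non-negative ratio (full precision; report with
#'   [round_half_up()] to 1 decimal).
#' @examples
#' round_half_up(rate_ratio(51.4, 34.3), 1)  # 1.5
#' @export
rate_ratio <- function(group_rate, reference_rate) {
  if (any(reference_rate <= 0)) {
    stop("`reference_rate` must be > 0", call. = FALSE)
  }
  group_rate / reference_rate
}

#' Absolute and percent change between two time points
#'
#' @param value_start,value_end values at the start and end of the period.
#' @param percent compute the percent change (requires `value_start > 0`).
#' @return list with `absolute` (end - start) and `percent`
#'   (100 x (end - start)/start, or `NA` if not requested).
#' @examples
#' trend_change(1701976, 1879890)$absolute  # 177914
#' @export
trend_change <- function(value_start, value_end, percent = TRUE) {
  absolute <- value_end - value_start
  pct <- NA_real_
  if (percent) {
    if (any(value_start == 0)) {
      stop("percent change undefined for `value_start` = 0", call. = FALSE)
    }
    pct <- 100 * absolute / value_start
  }
  list(absolute = absolute, percent = pct)
}

# lower bound of an age band label ("15-19" -> 15, "90+" -> 90)
age_lower_bound <- function(age_group) {
  as.numeric(sub("^([0-9]+).*$", "\\1", age_group))
}

#' Working-age indicator for age-band labels
#'
#' @param age_group character labels like "15-19", "90+".
#' @return logical, `TRUE` where the band starts at age 15 or above.
#' @export
is_working_age <- function(age_group) {
  age_lower_bound(age_group) >= 15
}

#' Inequality records for one dimension
#'
#' Converts attributable-burden counts and populations into per-100 000
#' working-age rates by group along one dimension (sex, age_group or
#' region) and compares each group with the global working-age reference
#' rate via the rate difference and rate ratio.
#'
#' @param burden data.frame with `sex`, `age_group`, `iso3`, `value`
#'   columns (one measure/year; filter beforehand).
#' @param population data.frame `iso3, year, sex, age_group, pop` for the
#'   same year.
#' @param dimension one of "sex", "age_group", "region".
#' @param hierarchy data.frame `iso3, region`; required for
#'   `dimension = "region"`.
#' @return data.frame of class `inequality_records`: `group`,
#'   `rate`, `reference_rate`, `rate_difference`, `rate_ratio`, all at
#'   full precision (round with [round_half_up()] for reporting).
#' @export
inequality_records <- function(burden, population,
                               dimension = c("sex", "age_group", "region"),
                               hierarchy = NULL) {
  dimension <- match.arg(dimension)
  check_columns(burden, c("iso3", "sex", "age_group", "value"), "burden")
  check_columns(population, c("iso3", "sex", "age_group", "pop"), "population")
  wa_b <- burden[is_working_age(burden$age_group), , drop = FALSE]
  wa_p <- population[is_working_age(population$age_group), , drop = FALSE]
  if (dimension == "region") {
    if (is.null(hierarchy)) {
      stop("dimension 'region' requires `hierarchy`", call. = FALSE)
    }
    wa_b$region <- hierarchy$region[match(wa_b$iso3, hierarchy$iso3)]
    wa_p$region <- hierarchy$region[match(wa_p$iso3, hierarchy$iso3)]
  }
  ref_rate <- rate_per_100k(sum(wa_b$value), sum(wa_p$pop))
  g_count <- tapply(wa_b$value, wa_b[[dimension]], sum)
  g_pop <- tapply(wa_p$pop, wa_p[[dimension]], sum)
  groups <- sort(unique(c(names(g_count), names(g_pop))))
  cnt <- ifelse(is.na(g_count[groups]), 0, g_count[groups])
  pop <- g_pop[groups]
  if (anyNA(pop) || any(pop <= 0)) {
    stop("a group has zero or missing population", call. = FALSE)
  }
  rate <- rate_per_100k(as.numeric(cnt), as.numeric(pop))
  out <- data.frame(group = groups, rate = rate,
                    reference_rate = ref_rate,
                    rate_difference = rate_difference(rate, ref_rate),
                    rate_ratio = rate_ratio(rate, ref_rate),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("inequality_records", "data.frame")
  out
}

#' @export
print.inequality_records <- function(x, ...) {
  y <- as.data.frame(x)
  for (cl in c("rate", "reference_rate", "rate_difference", "rate_ratio")) {
    y[[cl]] <- round_half_up(y[[cl]], 1)
  }
  cat("per-100 000 working-age rates vs global reference (1-decimal)\n")
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}
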