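#' Lagged exposure window
#'
#' A block of `width` consecutive calendar years centred (for even widths)
#' on `burden_year - lag`. The default — a 10-year window around a 10-year
#' lag — encodes the convention that chronic-disease burden in year Y
#' reflects exposure accumulated a decade earlier: burden year 2016 maps
#' to exposure years 2001--2010.
#'
#' @param lag lag in years (>= 0).
#' @param width window width in years (>= 1).
#' @return list of class `lag_window`.
#' @examples
#' window_years(2016, lag_window(10, 10))  # 2001:2010
#' @export
lag_window <- function(lag = 10, width = 10) {
  if (lag < 0) stop_field("lag", "must be >= 0")
  if (width < 1) stop_field("width", "must be >= 1")
  structure(list(lag = lag, width = width), class = "lag_window")
}

#' @export
print.lag_window <- function(x, ...) {
  cat(sprintf("exposure window: %d year(s), lag %d\n", x$width, x$lag))
  invisible(x)
}

#' Calendar years of the exposure window for a burden year
#'
#' For even widths the window is the `width` consecutive years centred on
#' `burden_year - lag`; for odd widths the centre year sits in the middle.
#'
#' @param burden_year year for which burden is estimated.
#' @param window a [lag_window()].
#' @return integer vector of consecutive years (inclusive).
#' @examples
#' window_years(2016, lag_window(10, 10))  # 2001:2010
#' window_years(2016, lag_window(0, 1))    # 2016
#' @export
window_years <- function(burden_year, window = lag_window()) {
  stopifnot(inherits(window, "lag_window"), length(burden_year) == 1L)
  centre <- burden_year - window$lag
  start <- centre - floor(window$width / 2)
  seq.int(start, start + window$width - 1L)
}

#' Windowed exposure prevalence per stratum
#'
#' Arithmetic mean of the annual prevalences over the exposure window,
#' computed per stratum (all surface columns other than `year`,
#' `prevalence` and `se_logit` act as stratum keys). Strata whose surface
#' does not cover every window year are averaged over the available years
#' and flagged `extrapolated`.
#'
#' @param surface data.frame with at least `year` and `prevalence`
#'   (typically `iso3, year, prevalence, se_logit` from
#'   [predict.prevalence_fit()]).
#' @param burden_year burden year.
#' @param window a [lag_window()].
#' @return data.frame: stratum keys, `year` (= `burden_year`),
#'   `prevalence` (window mean), `se_logit` (mean of available cell SEs,
#'   if present), `extrapolated`.
#' @examples
#' surf <- data.frame(iso3 = "AAA", year = 2001:2010,
#'                    prevalence = seq(0.10, 0.28, by = 0.02))
#' windowed_prevalence(surf, 2016, lag_window(10, 10))$prevalence  # 0.19
#' @export
windowed_prevalence <- function(surface, burden_year, window = lag_window()) {
  check_columns(surface, c("year", "prevalence"), "surface")
  yrs <- window_years(burden_year, window)
  keys <- setdiff(names(surface), c("year", "prevalence", "se_logit",
                                    "extrapolated"))
  sub <- surface[surface$year %in% yrs, , drop = FALSE]
  if (!nrow(sub)) {
    stop(sprintf("surface has no years overlapping the window %d-%d",
                 min(yrs), max(yrs)), call. = FALSE)
  }
  key_id <- if (length(keys)) {
    interaction(sub[keys], drop = TRUE, lex.order = TRUE)
  } else {
    factor(rep("all", nrow(sub)))
  }
  n_y <- tapply(sub$year, key_id, function(y) length(unique(y)))
  p <- tapply(sub$prevalence, key_id, mean)
  out <- if (length(keys)) {
    u <- unique(sub[keys])
    u <- u[order(interaction(u, drop = TRUE, lex.order = TRUE)), , drop = FALSE]
    u
  } else {
    data.frame(row.names = seq_along(p))
  }
  out$year <- burden_year
  out$prevalence <- as.numeric(p[levels(key_id)])
  if ("se_logit" %in% names(surface)) {
    out$se_logit <- as.numeric(tapply(sub$se_logit, key_id, mean)[levels(key_id)])
  }
  out$extrapolated <- as.integer(n_y[levels(key_id)]) < length(yrs)
  rownames(out) <- NULL
  out
}
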