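#' Population attributable fraction, Levin's formula
#'
#' For a single exposed category with exposure prevalence P and relative
#' risk RR, the fraction of the outcome's burden attributable to the
#' exposure is
#' \deqn{PAF = \frac{P(RR-1)}{P(RR-1)+1}.}
#' This is the standard comparative-risk-assessment form comparing the
#' observed exposure distribution with a counterfactual of no exposure.
#'
#' @param prevalence exposure prevalence in \[0, 1\] (vectorised).
#' @param rr relative risk > 0 (vectorised, recycled against `prevalence`).
#' @return PAF values; in \[0, 1) for RR >= 1, negative for protective RR.
#' @examples
#' levin_paf(0.1, 1.35)  # 0.03382
#' levin_paf(0.5, 1)     # 0: null effect
#' @export
levin_paf <- function(prevalence, rr) {
  if (any(!is.finite(prevalence)) || any(prevalence < 0 | prevalence > 1)) {
    stop("`prevalence` must lie in [0, 1]", call. = FALSE)
  }
  if (any(!is.finite(rr)) || any(rr <= 0)) {
    stop("`rr` must be > 0", call. = FALSE)
  }
  num <- prevalence * (rr - 1)
  num / (num + 1)
}

#' Population attributable fraction by transfer
#'
#' The PAF implied by an external burden study: attributable count divided
#' by total count. An empty stratum (total = 0 with attributable = 0)
#' yields 0 with a warning.
#'
#' @param attributable attributable count(s), 0 <= attributable <= total.
#' @param total total count(s).
#' @return PAF in \[0, 1\].
#' @examples
#' transfer_paf(25, 100)  # 0.25
#' @export
transfer_paf <- function(attributable, total) {
  if (any(attributable < 0) || any(total < 0)) {
    stop("counts must be >= 0", call. = FALSE)
  }
  if (any(attributable > total)) {
    stop("`attributable` exceeds `total`", call. = FALSE)
  }
  empty <- total == 0
  if (any(empty)) warning("empty stratum (total = 0): PAF set to 0")
  out <- numeric(length(attributable))
  out[!empty] <- attributable[!empty] / total[!empty]
  out
}

#' Apply PAFs to burden envelopes
#'
#' Joins a PAF table to the total deaths/DALY envelopes of each pair's
#' outcome and multiplies: attributable value = PAF x envelope value. A
#' PAF given at a coarser granularity (e.g. country-year) applies
#' uniformly across the envelope's finer strata (sex, age). Envelope
#' cells with no matching PAF produce no output row.
#'
#' @param paf data.frame with columns `pair_id`, `paf`, plus any stratum
#'   keys among `iso3`, `year`, `sex`, `age_group`.
#' @param envelopes data.frame with columns
#'   `cause, iso3, year, sex, age_group, measure, value`.
#' @param pairs pair registry with columns `pair_id`, `outcome`,
#'   `measures` (comma-separated subset of "deaths,daly").
#' @return data.frame `pair_id, iso3, year, sex, age_group, measure, value`.
#' @examples
#' env <- data.frame(cause = "Stroke", iso3 = "AAA", year = 2016,
#'                   sex = "male", age_group = "40-44",
#'                   measure = "deaths", value = 1000)
#' paf <- data.frame(pair_id = "p", iso3 = "AAA", year = 2016, paf = 0.2)
#' reg <- data.frame(pair_id = "p", outcome = "Stroke", measures = "deaths")
#' attributable_burden(paf, env, reg)$value  # 200
#' @export
attributable_burden <- function(paf, envelopes, pairs) {
  check_columns(paf, c("pair_id", "paf"), "paf")
  check_columns(envelopes, c("cause", "iso3", "year", "sex", "age_group",
                             "measure", "value"), "envelopes")
  check_columns(pairs, c("pair_id", "outcome", "measures"), "pairs")
  if (any(paf$paf < 0 | paf$paf > 1)) {
    stop("PAF values must lie in [0, 1]", call. = FALSE)
  }
  used <- unique(paf$pair_id)
  reg <- pairs[pairs$pair_id %in% used, , drop = FALSE]
  missing_pairs <- setdiff(used, reg$pair_id)
  if (length(missing_pairs)) {
    stop(sprintf("pair(s) absent from registry: %s",
                 paste(missing_pairs, collapse = ", ")), call. = FALSE)
  }
  absent <- setdiff(reg$outcome, unique(envelopes$cause))
  if (length(absent)) {
    stop(sprintf("outcome(s) absent from envelopes: %s",
                 paste(absent, collapse = ", ")), call. = FALSE)
  }
  join_keys <- intersect(c("iso3", "year", "sex", "age_group"), names(paf))
  out <- lapply(seq_len(nrow(reg)), function(i) {
    pid <- reg$pair_id[i]
    meas <- trimws(strsplit(reg$measures[i], ",")[[1]])
    env <- envelopes[envelopes$cause == reg$outcome[i] &
                       envelopes$measure %in% meas, , drop = FALSE]
    pf <- paf[paf$pair_id == pid, c(join_keys, "paf"), drop = FALSE]
    if (anyDuplicated(pf[join_keys])) {
      stop(sprintf("duplicate PAF stratum for pair %s", pid), call. = FALSE)
    }
    m <- merge(env, pf, by = join_keys)
    if (!nrow(m)) return(NULL)
    data.frame(pair_id = pid, m[c("iso3", "year", "sex", "age_group",
                                  "measure")],
               value = m$value * m$paf, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(pair_id = character(), iso3 = character(),
                      year = integer(), sex = character(),
                      age_group = character(), measure = character(),
                      value = double())
  }
  res <- res[order(res$pair_id, res$iso3, res$year, res$sex, res$age_group,
                   res$measure), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Aggregate attributable burden
#'
#' Plain summation of attributable values over the requested grouping
#' keys. Summing across pairs follows the reporting convention of adding
#' all pairs' burdens without co-attribution adjustment. Requesting a
#' `region` grouping requires a `hierarchy` mapping.
#'
#' @param burden data.frame with a `value` column (e.g. from
#'   [attributable_burden()]).
#' @param by character vector of grouping keys; any column of `burden`,
#'   plus `region` when `hierarchy` is supplied.
#' @param hierarchy optional data.frame `iso3, region`.
#' @return data.frame of the grouping keys and summed `value`.
#' @export
aggregate_burden <- function(burden, by, hierarchy = NULL) {
  check_columns(burden, "value", "burden")
  if ("region" %in% by && !"region" %in% names(burden)) {
    if (is.null(hierarchy)) {
      stop("grouping by region requires `hierarchy`", call. = FALSE)
    }
    burden$region <- hierarchy$region[match(burden$iso3, hierarchy$iso3)]
    if (anyNA(burden$region)) {
      stop("country missing from hierarchy: ",
           paste(unique(burden$iso3[is.na(burden$region)]), collapse = ", "),
           call. = FALSE)
    }
  }
  bad <- setdiff(by, names(burden))
  if (length(bad)) {
    stop(sprintf("unknown grouping key(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  if (!nrow(burden)) {
    out <- burden[c(by, "value")]
    return(out)
  }
  out <- aggregate(burden["value"], burden[by], sum)
  out <- out[do.call(order, out[by]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pair with the largest attributable burden
#'
#' Arg-max over pairs of the summed attributable value for one measure
#' and year. Ties are broken by lexicographic pair_id (with a message).
#'
#' @param burden data.frame with `pair_id`, `measure`, `year`, `value`.
#' @param measure "deaths" or "daly".
#' @param year burden year.
#' @return list with `pair_id` and `value`.
#' @export
top_pair <- function(burden, measure, year) {
  check_columns(burden, c("pair_id", "measure", "year", "value"), "burden")
  sub <- burden[burden$measure == measure & burden$year == year, , drop = FALSE]
  if (!nrow(sub)) stop("no rows for the requested measure/year", call. = FALSE)
  tot <- aggregate_burden(sub, by = "pair_id")
  best <- tot[tot$value == max(tot$value), , drop = FALSE]
  if (nrow(best) > 1L) {
    message("tie for top pair; broken by pair_id order")
    best <- best[order(best$pair_id), , drop = FALSE]
  }
  list(pair_id = best$pair_id[1], value = best$value[1])
}
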