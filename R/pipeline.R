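#' Run the full attribution pipeline
#'
#' Orchestrates the estimation chain on an input bundle: fit the
#' hierarchical exposure model to surveys (only if the pair registry
#' contains prevalence/RR pairs), predict the exposure surface over the
#' lagged windows, compute windowed prevalences and Levin PAFs, join
#' transfer PAFs, apply all PAFs to the envelopes, aggregate, compute
#' sex/age/region inequality records, and bootstrap 95% uncertainty
#' ranges for the prevalence/RR pairs (transfer pairs carry fixed inputs
#' and get degenerate intervals).
#'
#' @param inputs either a directory containing the tidy CSV bundle
#'   (`surveys.csv`, `hierarchy.csv`, `envelopes.csv`, `population.csv`,
#'   `transfer_paf.csv`, `pairs.csv`) or an equivalent named list of
#'   data.frames (as produced by [simulate_scenario()]`$inputs`).
#' @param burden_years years to attribute burden for (must be covered by
#'   the envelopes).
#' @param window a [lag_window()].
#' @param n_draws bootstrap draws (>= 2).
#' @param seed integer seed controlling every random step.
#' @param out_dir optional output directory; when given, all result
#'   tables plus a machine-readable `run_log.txt` are written as CSV.
#'   Outputs are deterministic: identical inputs + seed give
#'   byte-identical files.
#' @return list with elements `fit` (the `prevalence_fit`, or NULL when
#'   no levin pair is present), `surface`, `windowed`, `paf`, `burden`
#'   (per-stratum attributable burden), `global` (per pair/measure/year
#'   totals), `ur` (totals with 95% UR columns), `global_ur` (all-pair
#'   totals with UR per measure/year), `inequality` (list of
#'   [inequality_records()] by dimension) and `log`.
#' @examples
#' sc <- simulate_scenario(scenario_config(seed = 3))
#' res <- run_pipeline(sc$inputs, burden_years = 2016, n_draws = 50,
#'                     seed = 3)
#' res$global_ur
#' @export
run_pipeline <- function(inputs, burden_years = 2016,
                         window = lag_window(), n_draws = 200, seed,
                         out_dir = NULL) {
  if (missing(seed)) stop("`seed` must be set explicitly", call. = FALSE)
  if (n_draws < 2) stop_field("n_draws", "must be >= 2")
  if (!length(burden_years)) stop_field("burden_years", "empty")
  if (is.character(inputs) && length(inputs) == 1L) {
    inputs <- read_bundle(inputs)
  }
  pairs <- inputs$pairs
  check_columns(pairs, c("pair_id", "outcome", "paf_mode", "measures"),
                "pairs")
  levin_pairs <- pairs[pairs$paf_mode == "levin", , drop = FALSE]
  log <- c(sprintf("attribwork %s",
                   as.character(utils::packageVersion("attribwork"))),
           sprintf("seed=%d n_draws=%d", as.integer(seed), n_draws),
           sprintf("burden_years=%s", paste(burden_years, collapse = ",")),
           sprintf("window lag=%d width=%d", window$lag, window$width))

  fit <- NULL; surface <- NULL; windowed <- NULL
  paf_levin <- NULL
  if (nrow(levin_pairs)) {
    stage <- "fit-exposure"
    fit <- pipeline_try(stage, fit_prevalence_model(inputs$surveys,
                                                    inputs$hierarchy))
    need_years <- sort(unique(unlist(lapply(burden_years, window_years,
                                            window = window))))
    surface <- pipeline_try("predict", predict(fit, years = need_years))
    windowed <- do.call(rbind, lapply(burden_years, function(by) {
      windowed_prevalence(surface[c("iso3", "year", "prevalence",
                                    "se_logit")], by, window)
    }))
    paf_levin <- do.call(rbind, lapply(seq_len(nrow(levin_pairs)), function(i) {
      data.frame(pair_id = levin_pairs$pair_id[i], iso3 = windowed$iso3,
                 year = windowed$year,
                 paf = levin_paf(windowed$prevalence,
                                 levin_pairs$rr_point[i]),
                 stringsAsFactors = FALSE)
    }))
    log <- c(log, sprintf("exposure model: %d surveys, %d countries",
                          fit$nobs, length(fit$ranef_country)))
  } else {
    log <- c(log, "no prevalence/RR pairs: exposure fitting skipped")
  }

  transfer <- inputs$transfer_paf
  if (!is.null(transfer) && nrow(transfer)) {
    transfer <- transfer[transfer$year %in% burden_years,
                         c("pair_id", "iso3", "year", "paf"), drop = FALSE]
  } else {
    transfer <- NULL
  }
  paf <- rbind(paf_levin, transfer)
  if (is.null(paf) || !nrow(paf)) {
    stop("pipeline stage paf: no PAFs to apply", call. = FALSE)
  }

  envelopes <- inputs$envelopes[inputs$envelopes$year %in% burden_years, ,
                                drop = FALSE]
  burden <- pipeline_try("attribute", attributable_burden(paf, envelopes,
                                                          pairs))
  global <- aggregate_burden(burden, by = c("pair_id", "measure", "year"))

  # bootstrap UR: exposure + RR uncertainty for levin pairs only
  ur <- global
  ur$ur_lower <- ur$value
  ur$ur_upper <- ur$value
  draws_by_cell <- list()  # per (measure, year): matrix draws of levin totals
  if (nrow(levin_pairs)) {
    env_country <- aggregate(
      envelopes["value"],
      envelopes[c("cause", "iso3", "year", "measure")], sum)
    for (by in burden_years) {
      w_by <- windowed[windowed$year == by, , drop = FALSE]
      pd <- prevalence_draws(w_by, n_draws, seed = as.integer(seed))
      for (i in seq_len(nrow(levin_pairs))) {
        pid <- levin_pairs$pair_id[i]
        rrd <- rr_draws(list(rr_point = levin_pairs$rr_point[i],
                             ci_low = levin_pairs$rr_lo[i],
                             ci_high = levin_pairs$rr_hi[i]),
                        n_draws, seed = as.integer(seed) + i)
        for (meas in trimws(strsplit(levin_pairs$measures[i], ",")[[1]])) {
          ev <- env_country[env_country$cause == levin_pairs$outcome[i] &
                              env_country$measure == meas &
                              env_country$year == by, , drop = FALSE]
          env_vec <- ev$value[match(w_by$iso3, ev$iso3)]
          env_vec[is.na(env_vec)] <- 0
          bd <- propagate_burden(pd, rrd, env_vec)
          totals <- colSums(bd$values)
          sel <- ur$pair_id == pid & ur$measure == meas & ur$year == by
          iv <- summarize_ur(totals, point = ur$value[sel])
          ur$ur_lower[sel] <- iv$lower
          ur$ur_upper[sel] <- iv$upper
          key <- paste(meas, by)
          draws_by_cell[[key]] <- rbind(draws_by_cell[[key]], totals)
        }
      }
    }
  }

  # all-pair totals: levin draws vary, transfer totals are fixed offsets
  glob_tot <- aggregate_burden(burden, by = c("measure", "year"))
  glob_tot$ur_lower <- glob_tot$value
  glob_tot$ur_upper <- glob_tot$value
  for (k in seq_len(nrow(glob_tot))) {
    key <- paste(glob_tot$measure[k], glob_tot$year[k])
    if (!is.null(draws_by_cell[[key]])) {
      levin_draws <- colSums(draws_by_cell[[key]])
      levin_point <- sum(ur$value[ur$pair_id %in% levin_pairs$pair_id &
                                    ur$measure == glob_tot$measure[k] &
                                    ur$year == glob_tot$year[k]])
      fixed <- glob_tot$value[k] - levin_point
      iv <- summarize_ur(fixed + levin_draws, point = glob_tot$value[k])
      glob_tot$ur_lower[k] <- iv$lower
      glob_tot$ur_upper[k] <- iv$upper
    }
  }

  inequality <- list()
  if (!is.null(inputs$population) && nrow(inputs$population)) {
    for (dim in c("sex", "age_group")) {
      by <- burden_years[length(burden_years)]
      b <- burden[burden$measure == "deaths" & burden$year == by, ,
                  drop = FALSE]
      p <- inputs$population[inputs$population$year == by, , drop = FALSE]
      if (nrow(b) && nrow(p)) {
        inequality[[dim]] <- inequality_records(b, p, dimension = dim)
      }
    }
  }
  log <- c(log, sprintf("attributed %d pair(s), %d stratum rows",
                        length(unique(burden$pair_id)), nrow(burden)))

  res <- list(fit = fit, surface = surface, windowed = windowed, paf = paf,
              burden = burden, global = global, ur = ur,
              global_ur = glob_tot, inequality = inequality, log = log)
  if (!is.null(out_dir)) write_results(res, out_dir)
  res
}

pipeline_try <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage %s: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Read a tidy-CSV input bundle from a directory
#'
#' @param dir directory holding `surveys.csv`, `hierarchy.csv`,
#'   `envelopes.csv`, `population.csv`, `transfer_paf.csv`, `pairs.csv`
#'   (surveys/transfer_paf/population optional).
#' @return named list of data.frames.
#' @export
read_bundle <- function(dir) {
  if (!dir.exists(dir)) stop("no such directory: ", dir, call. = FALSE)
  get <- function(name, required = TRUE) {
    p <- file.path(dir, paste0(name, ".csv"))
    if (!file.exists(p)) {
      if (required) stop("missing input file: ", basename(p), call. = FALSE)
      return(NULL)
    }
    read_table(p, name)
  }
  list(surveys = get("surveys", required = FALSE),
       hierarchy = get("hierarchy"),
       envelopes = get("envelopes"),
       population = get("population", required = FALSE),
       transfer_paf = get("transfer_paf", required = FALSE),
       pairs = get("pairs"))
}

write_results <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(res$surface)) {
    write_table(res$surface, file.path(out_dir, "exposure_surface.csv"))
  }
  write_table(res$paf, file.path(out_dir, "paf.csv"))
  write_table(res$burden, file.path(out_dir, "attributable_burden.csv"))
  write_table(res$ur, file.path(out_dir, "burden_with_ur.csv"))
  write_table(res$global_ur, file.path(out_dir, "burden_global.csv"))
  for (dim in names(res$inequality)) {
    write_table(as.data.frame(res$inequality[[dim]]),
                file.path(out_dir, paste0("inequality_", dim, ".csv")))
  }
  writeLines(res$log, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}
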