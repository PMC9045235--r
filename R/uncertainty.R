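#' Bootstrap draws of a relative risk
#'
#' Samples the RR from a lognormal with median `rr_point` and
#' `sdlog = (log(ci_high) - log(ci_low)) / (2 * 1.959964)`, the standard
#' parameterisation for a ratio measure from its published 95% CI. A
#' degenerate CI (low = high = point) yields constant draws.
#'
#' @param rr list or one-row data.frame with `rr_point`, `ci_low`,
#'   `ci_high` (0 < low <= point <= high).
#' @param n_draws number of draws (>= 2).
#' @param seed integer seed.
#' @return object of class `draw_set`: list with `values` (numeric
#'   vector), `n_draws`, `seed`.
#' @examples
#' d <- rr_draws(list(rr_point = 1.35, ci_low = 1.13, ci_high = 1.61),
#'               n_draws = 1000, seed = 1)
#' quantile(d$values, c(.025, .975))
#' @export
rr_draws <- function(rr, n_draws, seed) {
  lo <- rr$ci_low; hi <- rr$ci_high; pt <- rr$rr_point
  if (is.null(lo) || is.null(hi) || is.null(pt)) {
    stop("`rr` needs rr_point, ci_low, ci_high", call. = FALSE)
  }
  if (lo <= 0) stop("ci_low must be > 0", call. = FALSE)
  if (!(lo <= pt && pt <= hi)) {
    stop("require ci_low <= rr_point <= ci_high", call. = FALSE)
  }
  if (n_draws < 2) stop("n_draws must be >= 2", call. = FALSE)
  sdlog <- (log(hi) - log(lo)) / (2 * qnorm(0.975))
  values <- with_seed(seed, pt * exp(rnorm(n_draws, 0, sdlog)))
  structure(list(values = values, n_draws = n_draws, seed = seed),
            class = "draw_set")
}

#' Bootstrap draws of an exposure surface
#'
#' Per-cell normal draws on the logit scale around the surface's point
#' prevalence with its `se_logit`, back-transformed; all draws lie in
#' (0, 1).
#'
#' @param surface data.frame with `prevalence` and `se_logit` columns
#'   (plus any stratum keys, carried through as `cells`).
#' @param n_draws number of draws (>= 2).
#' @param seed integer seed.
#' @return `draw_set` whose `values` is an `n_cells x n_draws` matrix and
#'   whose `cells` holds the surface's key columns.
#' @export
prevalence_draws <- function(surface, n_draws, seed) {
  check_columns(surface, c("prevalence", "se_logit"), "surface")
  if (anyNA(surface$se_logit)) stop("missing se_logit", call. = FALSE)
  if (n_draws < 2) stop("n_draws must be >= 2", call. = FALSE)
  n <- nrow(surface)
  mu <- qlogis(surface$prevalence)
  values <- with_seed(seed, {
    eps <- matrix(rnorm(n * n_draws), n, n_draws)
    plogis(mu + eps * surface$se_logit)
  })
  cells <- surface[setdiff(names(surface), c("prevalence", "se_logit"))]
  structure(list(values = values, n_draws = n_draws, seed = seed,
                 cells = cells), class = "draw_set")
}

#' @export
print.draw_set <- function(x, ...) {
  dim_txt <- if (is.matrix(x$values)) {
    sprintf("%d cell(s) x %d draws", nrow(x$values), ncol(x$values))
  } else {
    sprintf("%d draws", length(x$values))
  }
  cat(sprintf("draw_set: %s (seed %s)\n", dim_txt, format(x$seed)))
  invisible(x)
}

#' Propagate prevalence and RR draws into attributable-burden draws
#'
#' For each bootstrap draw i, the Levin PAF is evaluated at prevalence
#' draw i and RR draw i for every cell, then multiplied by the cell's
#' (fixed) envelope value. Envelope uncertainty is not propagated.
#'
#' @param prev_draws cell-level `draw_set` from [prevalence_draws()].
#' @param rr_draws scalar `draw_set` from [rr_draws()] with the same
#'   number of draws.
#' @param envelope numeric vector of envelope values aligned with the
#'   prevalence cells.
#' @return `draw_set` with `values` an `n_cells x n_draws` burden matrix
#'   and the prevalence cells carried through.
#' @export
propagate_burden <- function(prev_draws, rr_draws, envelope) {
  stopifnot(inherits(prev_draws, "draw_set"), inherits(rr_draws, "draw_set"))
  if (prev_draws$n_draws != rr_draws$n_draws) {
    stop("draw-count mismatch between prevalence and RR draws", call. = FALSE)
  }
  P <- prev_draws$values
  if (!is.matrix(P)) P <- matrix(P, nrow = 1)
  if (length(envelope) != nrow(P)) {
    stop("envelope length must match the number of prevalence cells",
         call. = FALSE)
  }
  rrv <- rep(rr_draws$values, each = nrow(P))
  paf <- matrix(levin_paf(as.numeric(P), rrv), nrow(P), ncol(P))
  structure(list(values = paf * envelope, n_draws = prev_draws$n_draws,
                 seed = prev_draws$seed, cells = prev_draws$cells),
            class = "draw_set")
}

#' 95% uncertainty range from bootstrap draws
#'
#' Lower/upper limits are the empirical 2.5% and 97.5% quantiles of the
#' draws (linear-interpolation quantile definition, `type = 7`). The
#' point estimate is the computation at point inputs, passed through
#' unchanged — not the draw mean.
#'
#' @param draws numeric vector of draws, or a `draw_set`; a matrix-valued
#'   `draw_set` is first summed over cells (column sums) so the interval
#'   refers to the total.
#' @param point point estimate to attach.
#' @return list of class `uncertainty_interval`: `point`, `lower`,
#'   `upper`, `level` (fixed at 95).
#' @examples
#' summarize_ur(1:1000, point = 500)  # lower 25.975, upper 975.025
#' @export
summarize_ur <- function(draws, point = NULL) {
  if (inherits(draws, "draw_set")) draws <- draws$values
  if (is.matrix(draws)) draws <- colSums(draws)
  if (!length(draws)) stop("empty draws", call. = FALSE)
  if (length(draws) < 40) {
    warning("fewer than 40 draws: the 95% interval is poorly resolved")
  }
  q <- quantile(draws, c(0.025, 0.975), names = FALSE, type = 7)
  structure(list(point = point, lower = q[1], upper = q[2], level = 95),
            class = "uncertainty_interval")
}

#' @export
print.uncertainty_interval <- function(x, ...) {
  pt <- if (is.null(x$point)) "" else sprintf("%g ", x$point)
  cat(sprintf("%s(95%% UR %g-%g)\n", pt, x$lower, x$upper))
  invisible(x)
}
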