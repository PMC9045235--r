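#' Fit a hierarchical exposure-prevalence model to survey data
#'
#' Models the logit of each survey's observed prevalence as
#' \deqn{\mathrm{logit}(p_{ct}) = \beta_0 + u_{r(c)} + u_c +
#'   \beta_1 (t - t_0),}
#' with independent region and country random intercepts and a global
#' linear year trend, fitted as a weighted linear mixed model
#' (`lme4::lmer`) with survey sample sizes as weights; country and region
#' effects are the empirical-Bayes (BLUP) estimates. The reference year
#' \eqn{t_0} is the midpoint of the observed year range.
#'
#' Degenerate inputs degrade gracefully: with a single region the region
#' term is dropped; with a single country (or zero-variance observations)
#' the model reduces to a weighted least-squares trend fit and the random
#' variances are reported as 0. Observed prevalences of exactly 0 or 1
#' are clamped to `[1/(4 n_s), 1 - 1/(4 n_s)]` before the logit.
#'
#' @param observations data.frame with columns
#'   `iso3, year, prevalence, sample_size`.
#' @param hierarchy data.frame `iso3, region` covering every observed
#'   country (and any country prediction is later requested for).
#' @return object of class `prevalence_fit` with methods
#'   [print.prevalence_fit()], [summary.prevalence_fit()],
#'   [coef.prevalence_fit()], [predict.prevalence_fit()],
#'   [residuals.prevalence_fit()], [plot.prevalence_fit()] and
#'   [simulate.prevalence_fit()].
#' @examples
#' sc <- simulate_scenario(scenario_config(seed = 7))
#' fit <- fit_prevalence_model(sc$inputs$surveys, sc$inputs$hierarchy)
#' fit
#' @export
fit_prevalence_model <- function(observations, hierarchy) {
  check_columns(observations, c("iso3", "year", "prevalence", "sample_size"),
                "observations")
  check_columns(hierarchy, c("iso3", "region"), "hierarchy")
  if (!nrow(observations)) stop("no observations", call. = FALSE)
  if (any(observations$prevalence < 0 | observations$prevalence > 1)) {
    stop("prevalence outside [0, 1]", call. = FALSE)
  }
  if (any(observations$sample_size <= 0)) {
    stop("sample_size must be > 0", call. = FALSE)
  }
  unknown <- setdiff(unique(observations$iso3), hierarchy$iso3)
  if (length(unknown)) {
    stop("country missing from hierarchy: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }

  d <- observations
  # continuity clamp away from 0/1 so the logit is finite
  lo <- 1 / (4 * d$sample_size)
  d$p_clamped <- pmin(pmax(d$prevalence, lo), 1 - lo)
  d$y <- qlogis(d$p_clamped)
  d$region <- hierarchy$region[match(d$iso3, hierarchy$iso3)]
  ref_year <- mean(range(d$year))
  d$year_c <- d$year - ref_year
  d$w <- d$sample_size

  n_country <- length(unique(d$iso3))
  n_region <- length(unique(d$region))
  constant <- var(d$y) < 1e-12 || is.na(var(d$y))
  multi_year <- length(unique(d$year)) > 1L

  zero_vc <- function() c(region = 0, country = 0, residual = 0)
  if (n_country < 2L || constant) {
    form <- if (multi_year) y ~ year_c else y ~ 1
    model <- lm(form, data = d, weights = w)
    type <- "lm"
    beta <- coef(model)
    fe <- c(intercept = unname(beta[1]),
            trend = if (multi_year) unname(beta[2]) else 0)
    V <- vcov(model)
    if (!multi_year) V <- cbind(rbind(V, 0), 0)  # pad trend row/col
    re_region <- setNames(rep(0, n_region), unique(d$region))
    re_country <- setNames(rep(0, n_country), unique(d$iso3))
    pv_region <- re_region
    pv_country <- re_country
    vc <- zero_vc()
    vc["residual"] <- sigma(model)^2
  } else {
    form <- if (n_region >= 2L) {
      y ~ year_c + (1 | region) + (1 | iso3)
    } else {
      y ~ year_c + (1 | iso3)
    }
    model <- suppressMessages(lme4::lmer(
      form, data = d, weights = w, REML = TRUE,
      control = lme4::lmerControl(calc.derivs = FALSE,
                                  check.conv.singular = "ignore")
    ))
    type <- if (n_region >= 2L) "lmm2" else "lmm1"
    b <- lme4::fixef(model)
    fe <- c(intercept = unname(b["(Intercept)"]), trend = unname(b["year_c"]))
    V <- as.matrix(vcov(model))
    re <- lme4::ranef(model, condVar = TRUE)
    blup <- function(term) {
      if (is.null(re[[term]])) return(NULL)
      setNames(re[[term]][[1]], rownames(re[[term]]))
    }
    pvar <- function(term) {
      if (is.null(re[[term]])) return(NULL)
      setNames(as.numeric(attr(re[[term]], "postVar")[1, 1, ]),
               rownames(re[[term]]))
    }
    re_country <- blup("iso3")
    pv_country <- pvar("iso3")
    re_region <- blup("region")
    pv_region <- pvar("region")
    vcs <- as.data.frame(lme4::VarCorr(model))
    vc <- zero_vc()
    vc["country"] <- vcs$vcov[match("iso3", vcs$grp)]
    vc["region"] <- if ("region" %in% vcs$grp) vcs$vcov[match("region", vcs$grp)] else 0
    vc["residual"] <- sigma(model)^2
    if (is.null(re_region)) {
      re_region <- setNames(rep(0, n_region), unique(d$region))
      pv_region <- re_region
    }
  }

  # Joint conditional covariance of the random effects,
  #   Var(b | y) = sigma^2 * Lambda (Lambda' Z' W Z Lambda + I)^-1 Lambda',
  # needed because country and region BLUP errors are strongly
  # anti-correlated: the per-term conditional variances alone would
  # grossly overstate the uncertainty of their sum.
  vb <- NULL
  if (type != "lm") {
    Lt <- lme4::getME(model, "Lambdat")
    Zt <- lme4::getME(model, "Zt")
    LZ <- Lt %*% Zt
    A <- Matrix::tcrossprod(LZ %*% Matrix::Diagonal(x = sqrt(d$w)))
    Vu <- sigma(model)^2 * Matrix::solve(A + Matrix::Diagonal(nrow(A)))
    vb <- as.matrix(Matrix::t(Lt) %*% Vu %*% Lt)
    dimnames(vb) <- list(rownames(Zt), rownames(Zt))
  }

  structure(list(
    model = model, type = type, fixef = fe, vcov_fixef = V,
    ranef_region = re_region, ranef_country = re_country,
    postvar_region = pv_region, postvar_country = pv_country,
    condcov_ranef = vb,
    varcomp = vc, hierarchy = hierarchy, ref_year = ref_year,
    year_range = range(d$year), data = d, nobs = nrow(d),
    call = match.call()
  ), class = "prevalence_fit")
}

#' @export
print.prevalence_fit <- function(x, ...) {
  cat("Hierarchical exposure-prevalence model (logit scale)\n")
  cat(sprintf("  %d surveys, %d countries, %d regions; years %d-%d\n",
              x$nobs, length(x$ranef_country), length(x$ranef_region),
              x$year_range[1], x$year_range[2]))
  cat(sprintf("  intercept %.4f (prevalence %.4f at year %.1f), trend %+.5f/yr\n",
              x$fixef["intercept"], plogis(x$fixef["intercept"]),
              x$ref_year, x$fixef["trend"]))
  cat(sprintf("  SD(region) %.3f  SD(country) %.3f  residual SD %.3f\n",
              sqrt(x$varcomp["region"]), sqrt(x$varcomp["country"]),
              sqrt(x$varcomp["residual"])))
  invisible(x)
}

#' @export
coef.prevalence_fit <- function(object, ...) {
  list(fixed = object$fixef, region = object$ranef_region,
       country = object$ranef_country)
}

#' Summary of a prevalence fit
#'
#' @param object a `prevalence_fit`.
#' @param ... unused.
#' @return list with fixed effects and their SEs, variance components and
#'   the per-country effects, printed compactly.
#' @export
summary.prevalence_fit <- function(object, ...) {
  se <- sqrt(diag(object$vcov_fixef))[seq_along(object$fixef)]
  out <- list(
    fixef = data.frame(estimate = unname(object$fixef), se = unname(se),
                       row.names = names(object$fixef)),
    varcomp = object$varcomp,
    region = object$ranef_region,
    country = object$ranef_country,
    nobs = object$nobs
  )
  class(out) <- "summary.prevalence_fit"
  out
}

#' @export
print.summary.prevalence_fit <- function(x, ...) {
  cat("Fixed effects (logit scale):\n")
  print(round(x$fixef, 5))
  cat("\nVariance components:\n")
  print(round(x$varcomp, 5))
  cat("\nRegion effects:\n")
  print(round(x$region, 4))
  cat("\nCountry effects:\n")
  print(round(x$country, 4))
  invisible(x)
}

#' Predict the exposure-prevalence surface
#'
#' Evaluates the fitted model over a country-by-year grid. The linear
#' predictor is `intercept + trend*(year - ref) + region BLUP + country
#' BLUP`; its standard error combines the fixed-effect covariance with
#' the conditional (posterior) variances of the BLUPs. Countries never
#' observed but present in `hierarchy` are predicted from their region
#' with the full country-level variance added. Years outside the fitted
#' range extrapolate linearly on the logit scale and are flagged.
#'
#' @param object a `prevalence_fit`.
#' @param iso3 countries to predict (default: all fitted countries).
#' @param years calendar years (default: fitted year range).
#' @param level coverage level of the prediction interval.
#' @param ... unused.
#' @return data.frame `iso3, year, prevalence, se_logit, lwr, upr,
#'   extrapolated`; prevalences and interval bounds in \[0, 1\].
#' @export
predict.prevalence_fit <- function(object,
                                   iso3 = names(object$ranef_country),
                                   years = seq(object$year_range[1],
                                               object$year_range[2]),
                                   level = 0.95, ...) {
  hier <- object$hierarchy
  unknown <- setdiff(iso3, hier$iso3)
  if (length(unknown)) {
    stop("country absent from hierarchy: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  grid <- expand.grid(iso3 = iso3, year = years,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(grid$iso3, grid$year), , drop = FALSE]
  region <- hier$region[match(grid$iso3, hier$iso3)]

  u_c <- object$ranef_country[grid$iso3]
  pv_c <- object$postvar_country[grid$iso3]
  seen_c <- grid$iso3 %in% names(object$ranef_country)
  u_c[!seen_c] <- 0
  pv_c[!seen_c] <- object$varcomp["country"]

  u_r <- object$ranef_region[region]
  pv_r <- object$postvar_region[region]
  seen_r <- region %in% names(object$ranef_region)
  u_r[!seen_r] <- 0
  pv_r[!seen_r] <- object$varcomp["region"]

  yc <- grid$year - object$ref_year
  eta <- object$fixef["intercept"] + object$fixef["trend"] * yc + u_r + u_c
  X <- cbind(1, yc)
  var_fix <- rowSums((X %*% object$vcov_fixef) * X)
  # For observed countries the intercept's sampling error is absorbed by
  # the BLUPs (their sum is estimated far more precisely than either
  # part), so the cell variance is the joint conditional variance of
  # (region + country) effects plus the trend-slope contribution. The
  # full fixed-effect variance enters only for countries without data.
  var_trend <- yc^2 * object$vcov_fixef[2, 2]
  vb <- object$condcov_ranef
  var_re <- pv_r + pv_c  # fallback: per-term conditional variances
  if (!is.null(vb)) {
    rn <- rownames(vb)
    ic <- match(grid$iso3, rn)
    ir <- match(region, rn)
    has_c <- !is.na(ic)
    has_r <- !is.na(ir)
    v <- numeric(nrow(grid))
    v[has_c] <- vb[cbind(ic[has_c], ic[has_c])]
    v[!has_c] <- object$varcomp["country"]
    v[has_r] <- v[has_r] + vb[cbind(ir[has_r], ir[has_r])]
    both <- has_c & has_r
    v[both] <- v[both] + 2 * vb[cbind(ic[both], ir[both])]
    if (object$type == "lmm2") v[!has_r] <- v[!has_r] + object$varcomp["region"]
    var_re <- v
  }
  se2 <- ifelse(seen_c, var_re + var_trend, var_fix + var_re)
  se <- sqrt(pmax(se2, 0))
  z <- qnorm(1 - (1 - level) / 2)
  out <- data.frame(
    iso3 = grid$iso3, year = grid$year,
    prevalence = plogis(as.numeric(eta)),
    se_logit = as.numeric(se),
    lwr = plogis(as.numeric(eta - z * se)),
    upr = plogis(as.numeric(eta + z * se)),
    extrapolated = grid$year < object$year_range[1] |
      grid$year > object$year_range[2],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' @export
fitted.prevalence_fit <- function(object, ...) {
  # fitted values for the observed design rows
  sur <- predict(object, iso3 = unique(object$data$iso3),
                 years = unique(object$data$year))
  sur$prevalence[match(paste(object$data$iso3, object$data$year),
                       paste(sur$iso3, sur$year))]
}

#' Residuals on the logit or response scale
#'
#' @param object a `prevalence_fit`.
#' @param scale "logit" (default) or "response" (prevalence difference).
#' @param ... unused.
#' @return numeric vector, one element per observation.
#' @export
residuals.prevalence_fit <- function(object, scale = c("logit", "response"),
                                     ...) {
  scale <- match.arg(scale)
  fit_p <- fitted(object)
  if (scale == "response") {
    object$data$prevalence - fit_p
  } else {
    object$data$y - qlogis(fit_p)
  }
}

#' Plot observed surveys against the fitted surface
#'
#' One panel: observed survey prevalences (points, area proportional to
#' sample size) and fitted country trajectories (lines).
#'
#' @param x a `prevalence_fit`.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `x`.
#' @export
plot.prevalence_fit <- function(x, ...) {
  d <- x$data
  sur <- predict(x)
  graphics::plot(d$year, d$prevalence, pch = 16,
                 col = grDevices::grey(0.4, 0.5),
                 cex = 0.5 + sqrt(d$w / max(d$w)),
                 xlab = "year", ylab = "exposure prevalence", ...)
  for (cc in unique(sur$iso3)) {
    s <- sur[sur$iso3 == cc, ]
    graphics::lines(s$year, s$prevalence, col = "steelblue")
  }
  invisible(x)
}

#' Simulate survey observations from a fitted prevalence model
#'
#' Parametric bootstrap: draws new observed prevalences for the fitted
#' design (same countries, years, sample sizes) from a binomial around
#' the fitted surface.
#'
#' @param object a `prevalence_fit`.
#' @param nsim number of simulated data sets.
#' @param seed integer seed.
#' @param ... unused.
#' @return list of `nsim` data.frames shaped like the fitting data.
#' @export
simulate.prevalence_fit <- function(object, nsim = 1, seed = 1L, ...) {
  p <- fitted(object)
  n <- object$data$sample_size
  with_seed(seed, lapply(seq_len(nsim), function(i) {
    data.frame(iso3 = object$data$iso3, year = object$data$year,
               prevalence = rbinom(length(p), n, p) / n,
               sample_size = n, stringsAsFactors = FALSE)
  }))
}
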