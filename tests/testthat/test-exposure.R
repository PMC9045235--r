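make_obs <- function(iso3, years, p, n = 2000) {
  g <- expand.grid(iso3 = iso3, year = years, KEEP.OUT.ATTRS = FALSE,
                   stringsAsFactors = FALSE)
  g$prevalence <- p
  g$sample_size <- n
  g
}

test_that("constant noise-free surveys reproduce the constant", {
  obs <- make_obs(c("AAA", "AAB", "AAC", "AAD"), 2000:2010, p = 0.5)
  hier <- data.frame(iso3 = c("AAA", "AAB", "AAC", "AAD"),
                     region = c("R1", "R1", "R2", "R2"))
  fit <- fit_prevalence_model(obs, hier)
  sur <- predict(fit)
  expect_true(all(abs(sur$prevalence - 0.5) < 1e-6))
  expect_equal(unname(fit$varcomp[c("region", "country")]), c(0, 0))
})

test_that("noise-free logit-linear data are recovered exactly", {
  iso3 <- c("AAA", "AAB", "AAC", "AAD", "AAE", "AAF")
  hier <- data.frame(iso3 = iso3, region = rep(c("R1", "R2", "R3"), each = 2))
  u_r <- c(R1 = -0.4, R2 = 0.1, R3 = 0.3)
  u_c <- seq(-0.25, 0.25, by = 0.1)
  eta <- function(c_i, yr) -1.5 + u_r[hier$region[c_i]] + u_c[c_i] +
    0.02 * (yr - 2000)
  obs <- do.call(rbind, lapply(seq_along(iso3), function(i) {
    data.frame(iso3 = iso3[i], year = 1990:2010,
               prevalence = plogis(eta(i, 1990:2010)), sample_size = 5000)
  }))
  fit <- fit_prevalence_model(obs, hier)
  sur <- predict(fit)
  truth <- plogis(unlist(lapply(seq_along(iso3),
                                function(i) eta(i, 1990:2010))))
  sur <- sur[order(sur$iso3, sur$year), ]
  expect_true(all(abs(sur$prevalence - truth) < 1e-6))
})

test_that("a single country degrades to a weighted trend fit", {
  obs <- make_obs("AAA", 2000:2010, p = plogis(-1 + 0.05 * (2000:2010 - 2005)))
  hier <- data.frame(iso3 = "AAA", region = "R1")
  fit <- fit_prevalence_model(obs, hier)
  expect_identical(fit$type, "lm")
  expect_equal(unname(fit$varcomp["region"]), 0)
  expect_equal(unname(fit$varcomp["country"]), 0)
  expect_true(all(abs(predict(fit, years = 2000:2010)$prevalence -
                        obs$prevalence) < 1e-6))
})

test_that("prevalences of exactly 0 and 1 are clamped, not fatal", {
  obs <- make_obs(c("AAA", "AAB"), 2000:2005, p = 0.3, n = 100)
  obs$prevalence[1] <- 0
  obs$prevalence[2] <- 1
  hier <- data.frame(iso3 = c("AAA", "AAB"), region = c("R1", "R1"))
  fit <- fit_prevalence_model(obs, hier)
  expect_true(all(is.finite(fit$data$y)))
  expect_true(all(predict(fit)$prevalence > 0 & predict(fit)$prevalence < 1))
})

test_that("fit-time validation names the offending country", {
  obs <- make_obs(c("AAA", "ZZZ"), 2000:2002, p = 0.2)
  hier <- data.frame(iso3 = "AAA", region = "R1")
  expect_error(fit_prevalence_model(obs, hier), "ZZZ")
  expect_error(fit_prevalence_model(obs[0, ], hier), "observations")
})

test_that("in-sample prediction is consistent and trends are monotone", {
  sc <- tiny_scenario(seed = 21)
  fit <- fit_prevalence_model(sc$inputs$surveys, sc$inputs$hierarchy)
  sur <- predict(fit)
  f <- fitted(fit)
  d <- fit$data
  cell <- sur$prevalence[match(paste(d$iso3, d$year),
                               paste(sur$iso3, sur$year))]
  expect_equal(f, cell)
  # monotone transform: the sign of the fitted logit trend orders every
  # country's predicted trajectory
  ord <- if (fit$fixef["trend"] >= 0) 1 else -1
  for (cc in unique(sur$iso3)) {
    p <- sur$prevalence[sur$iso3 == cc][order(sur$year[sur$iso3 == cc])]
    expect_true(all(ord * diff(p) >= -1e-12))
  }
})

test_that("predictions flag extrapolated years and unknown countries error", {
  sc <- tiny_scenario(seed = 22)
  fit <- fit_prevalence_model(sc$inputs$surveys, sc$inputs$hierarchy)
  yrs <- (fit$year_range[1] - 3):(fit$year_range[2] + 2)
  sur <- predict(fit, iso3 = "AAA", years = yrs)
  expect_identical(sur$extrapolated,
                   yrs < fit$year_range[1] | yrs > fit$year_range[2])
  expect_error(predict(fit, iso3 = "QQQ"), "QQQ")
})

test_that("a country in the hierarchy but without surveys is predictable", {
  sc <- tiny_scenario(seed = 23)
  obs <- sc$inputs$surveys
  held_out <- "AAB"
  fit <- fit_prevalence_model(obs[obs$iso3 != held_out, ],
                              sc$inputs$hierarchy)
  sur <- predict(fit, iso3 = held_out, years = 2000:2005)
  expect_true(all(sur$prevalence > 0 & sur$prevalence < 1))
  # no data: wider uncertainty than a fitted country
  sur_in <- predict(fit, iso3 = "AAA", years = 2000:2005)
  expect_true(all(sur$se_logit > sur_in$se_logit))
})

test_that("residuals and simulate round-trip the fitting data shape", {
  sc <- tiny_scenario(seed = 24)
  fit <- fit_prevalence_model(sc$inputs$surveys, sc$inputs$hierarchy)
  r <- residuals(fit)
  expect_length(r, fit$nobs)
  expect_lt(abs(mean(residuals(fit, scale = "response"))), 0.05)
  sims <- simulate(fit, nsim = 2, seed = 4)
  expect_length(sims, 2)
  expect_identical(dim(sims[[1]]), dim(sc$inputs$surveys))
  expect_true(all(sims[[1]]$prevalence >= 0 & sims[[1]]$prevalence <= 1))
})
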