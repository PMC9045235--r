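test_that("Levin PAF closed form and edge cases", {
  expect_equal(levin_paf(0, 1.35), 0)
  expect_equal(levin_paf(0.5, 1), 0)
  expect_equal(levin_paf(0.1, 1.35), 0.1 * 0.35 / (0.1 * 0.35 + 1))
  expect_equal(levin_paf(0.1, 1.35), 0.033816, tolerance = 1e-4)
  expect_error(levin_paf(0.1, 0), "rr")
  expect_error(levin_paf(-0.2, 1.2), "prevalence")
  expect_error(levin_paf(1.2, 1.2), "prevalence")
})

test_that("Levin PAF is monotone in P and RR and saturates at 1", {
  p <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(levin_paf(p, 1.5)) > 0))
  rr <- seq(1.01, 5, by = 0.25)
  expect_true(all(diff(levin_paf(0.3, rr)) > 0))
  expect_equal(levin_paf(0.3, 1e9), 1, tolerance = 1e-8)
  expect_true(all(levin_paf(p, 1.35) >= 0 & levin_paf(p, 1.35) < 1))
})

test_that("Levin PAF agrees with a cohort-simulation oracle", {
  set.seed(101)
  P <- 0.1; RR <- 1.35
  sim <- cohort_paf(P, RR, n = 1e6)
  expect_lt(abs(levin_paf(P, RR) - sim$paf), 3 * sim$se)
})

test_that("transfer PAF is the attributable share with guarded edges", {
  expect_equal(transfer_paf(0, 100), 0)
  expect_equal(transfer_paf(25, 100), 0.25)
  expect_warning(z <- transfer_paf(0, 0), "empty stratum")
  expect_equal(z, 0)
  expect_error(transfer_paf(30, 20), "exceeds")
  expect_error(transfer_paf(-1, 10), ">= 0")
})

test_that("attributable burden is PAF times envelope", {
  env <- one_cell_envelope("Stroke", 1000)
  reg <- data.frame(pair_id = "p1", outcome = "Stroke", measures = "deaths")
  paf <- data.frame(pair_id = "p1", iso3 = "AAA", year = 2016, paf = 0.2)
  out <- attributable_burden(paf, env, reg)
  expect_equal(out$value, 200)
  paf0 <- transform(paf, paf = 0)
  expect_true(all(attributable_burden(paf0, env, reg)$value == 0))
  # larger PAF, larger attributable share of the same envelope
  v <- vapply(c(0.1, 0.2, 0.4), function(f) {
    attributable_burden(transform(paf, paf = f), env, reg)$value
  }, numeric(1))
  expect_true(all(diff(v) > 0))
})

test_that("country-level PAFs apply uniformly across sex and age strata", {
  env <- rbind(one_cell_envelope("Stroke", 1000, sex = "male"),
               one_cell_envelope("Stroke", 600, sex = "female"),
               one_cell_envelope("Stroke", 400, sex = "male",
                                 age_group = "60-64"))
  reg <- data.frame(pair_id = "p1", outcome = "Stroke", measures = "deaths")
  paf <- data.frame(pair_id = "p1", iso3 = "AAA", year = 2016, paf = 0.1)
  out <- attributable_burden(paf, env, reg)
  expect_equal(nrow(out), 3)
  expect_equal(sum(out$value), 0.1 * 2000)
})

test_that("attribution validates outcomes, keys and PAF range", {
  env <- one_cell_envelope("Stroke", 1000)
  reg <- data.frame(pair_id = "p1", outcome = "Ischemic heart disease",
                    measures = "deaths")
  paf <- data.frame(pair_id = "p1", iso3 = "AAA", year = 2016, paf = 0.2)
  expect_error(attributable_burden(paf, env, reg),
               "Ischemic heart disease")
  reg2 <- data.frame(pair_id = "p1", outcome = "Stroke", measures = "deaths")
  expect_error(attributable_burden(rbind(paf, paf), env, reg2), "duplicate")
  expect_error(attributable_burden(transform(paf, paf = 1.2), env, reg2),
               "\\[0, 1\\]")
  # a missing envelope cell yields no row rather than an error
  paf_two <- rbind(paf, transform(paf, iso3 = "AAB"))
  out <- attributable_burden(paf_two, env, reg2)
  expect_equal(out$iso3, "AAA")
})

test_that("zero envelopes for non-fatal outcomes are processed silently", {
  env <- one_cell_envelope("Other hearing loss", 0)
  reg <- data.frame(pair_id = "noise", outcome = "Other hearing loss",
                    measures = "deaths,daly")
  paf <- data.frame(pair_id = "noise", iso3 = "AAA", year = 2016, paf = 0.3)
  out <- attributable_burden(paf, env, reg)
  expect_equal(out$value, 0)
})

test_that("aggregation is exactly additive and order-free", {
  sc <- tiny_scenario(seed = 41)
  burden <- sc$truth$burden
  hier <- sc$inputs$hierarchy
  global <- aggregate_burden(burden, by = "measure")
  via_region <- aggregate_burden(burden, by = c("region", "measure"),
                                 hierarchy = hier)
  via_pair <- aggregate_burden(burden, by = c("pair_id", "measure"))
  for (m in unique(global$measure)) {
    g <- global$value[global$measure == m]
    expect_equal(sum(via_region$value[via_region$measure == m]), g,
                 tolerance = 1e-9)
    expect_equal(sum(via_pair$value[via_pair$measure == m]), g,
                 tolerance = 1e-9)
  }
  one <- burden[5, ]
  agg <- aggregate_burden(one, by = c("pair_id", "iso3", "year", "sex",
                                      "age_group", "measure"))
  expect_equal(agg$value, one$value)
  expect_error(aggregate_burden(burden, by = "planet"), "unknown grouping")
  expect_error(aggregate_burden(burden, by = "region"), "hierarchy")
})

test_that("top_pair returns the arg-max with lexicographic tie-breaks", {
  b <- data.frame(pair_id = c("b", "a", "c"), measure = "deaths",
                  year = 2016, value = c(5, 10, 10))
  expect_message(tp <- top_pair(b, "deaths", 2016), "tie")
  expect_equal(tp$pair_id, "a")
  expect_equal(tp$value, 10)
  single <- b[1, ]
  expect_equal(top_pair(single, "deaths", 2016)$pair_id, "b")
  expect_error(top_pair(b, "daly", 2016), "no rows")
})
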