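test_that("under-reporting adjustment divides by one minus the URR", {
  expect_equal(adjust_underreporting(90, 0.10), 100)
  expect_equal(adjust_underreporting(1234, 0), 1234)
  expect_equal(adjust_underreporting(266331, 0.25), 355108)
  expect_error(adjust_underreporting(10, 1), "\\[0, 1\\)")
  expect_error(adjust_underreporting(-1, 0.1), "non-negative")
  # monotone in URR
  urr <- seq(0, 0.9, by = 0.1)
  expect_true(all(diff(adjust_underreporting(100, urr)) > 0))
})

test_that("adjustment inverts binomial thinning in expectation", {
  set.seed(8)
  nrep <- 1000
  true_total <- 5000
  urr <- 0.25
  reported <- stats::rbinom(nrep, true_total, 1 - urr)
  adjusted <- adjust_underreporting(reported, urr)
  rel_err <- abs(mean(adjusted) - true_total) / true_total
  expect_lt(rel_err, 0.01)
})

test_that("URR extrapolation reproduces constants and straight lines", {
  yrs <- 2006:2017
  sched <- tidyr::expand_grid(region = "eastern", urban = TRUE, year = yrs)
  # constant schedule stays constant
  s1 <- dplyr::mutate(sched, urr = 0.10)
  e1 <- extrapolate_urr(s1, to_year = 2020)
  expect_equal(e1$urr[e1$year %in% 2018:2020], rep(0.10, 3), tolerance = 1e-8)
  # exact line 0.20 at 2006 declining 0.01/yr: 0.08 at 2018
  s2 <- dplyr::mutate(sched, urr = 0.20 - 0.01 * (year - 2006))
  e2 <- extrapolate_urr(s2, to_year = 2020)
  expect_equal(e2$urr[e2$year == 2018], 0.08, tolerance = 1e-8)
  # steep decline clamps at zero
  s3 <- dplyr::mutate(sched, urr = pmax(0, 0.12 - 0.012 * (year - 2006)))
  e3 <- extrapolate_urr(dplyr::filter(s3, year <= 2015), to_year = 2020)
  expect_true(all(e3$urr >= 0))
  expect_true(all(e3$urr <= 0.95))
  # too few observed years: carried forward with a warning
  s4 <- dplyr::filter(s1, year <= 2008)
  expect_warning(e4 <- extrapolate_urr(s4, to_year = 2010), "carrying")
  expect_equal(e4$urr[e4$year == 2010], 0.10)
})

test_that("quality filters apply the era- and system-specific thresholds", {
  mk <- function(rate_permille, years = 2010) {
    tibble::tibble(
      county_id = "x", region = "eastern", urban = TRUE, year = years,
      population = 1e5, deaths_all_adj = rate_permille / 1000 * 1e5
    )
  }
  # non-surveillance county at 2.9 per mille: excluded (3 per mille rule)
  r1 <- apply_quality_filters(mk(2.9), surveillance = FALSE)
  expect_equal(r1$exclusions$county_id, "x")
  expect_equal(nrow(r1$panel), 0)
  # surveillance county at 4.6 in 2010: retained (4.5 rule before 2013)
  r2 <- apply_quality_filters(mk(4.6), surveillance = TRUE)
  expect_equal(nrow(r2$exclusions), 0)
  # surveillance county at 4.8 in 2014: excluded (5 rule from 2013)
  r3 <- apply_quality_filters(mk(4.8, 2014), surveillance = TRUE)
  expect_equal(r3$exclusions$county_id, "x")
  # non-surveillance at 3.1: retained
  r4 <- apply_quality_filters(mk(3.1), surveillance = FALSE)
  expect_equal(nrow(r4$exclusions), 0)
  expect_error(apply_quality_filters(mk(3.1), surveillance = NA), "unknown")
})

test_that("retained and excluded counties partition the panel", {
  sim <- simulate_panel(tiny_config(seed = 3))
  panel <- adjust_panel(sim$panel, sim$urr)
  res <- apply_quality_filters(panel, surveillance = TRUE,
                               min_failing_years = 1)
  kept <- unique(res$panel$county_id)
  dropped <- res$exclusions$county_id
  expect_length(intersect(kept, dropped), 0)
  expect_setequal(c(kept, dropped), unique(panel$county_id))
  expect_equal(anyDuplicated(dropped), 0)
})

test_that("cause-specific rates multiply the all-cause rate by the cause share", {
  expect_equal(cvd_rate(0.010, 40, 100), 0.004)
  expect_equal(cvd_rate(0.5, 0, 10), 0)
  expect_equal(cvd_rate(0.0072, 356, 911), 0.0072 * 356 / 911)
  expect_error(cvd_rate(0.01, 5, 4), "exceed")
  z <- cvd_rate(0.01, c(0, 2), c(0, 4))
  expect_equal(as.numeric(z), c(0, 0.005))
  expect_equal(attr(z, "zero_denominator"), 1L)
})

test_that("direct standardization is a census-weighted average", {
  w <- tibble::tibble(age_group = c("young", "old"), weight = c(0.5, 0.5))
  expect_equal(asmr(c(young = 100, old = 300), w), 200)
  # constant rate is invariant
  expect_equal(asmr(c(young = 77, old = 77), w), 77)
  # five-band case against a hand-computed weighted sum
  w5 <- tibble::tibble(
    age_group = c("0-14", "15-44", "45-64", "65-74", "75+"),
    weight = c(0.18, 0.45, 0.22, 0.08, 0.07)
  )
  r5 <- c(`0-14` = 2, `15-44` = 20, `45-64` = 200, `65-74` = 800, `75+` = 3000)
  hand <- 0.18 * 2 + 0.45 * 20 + 0.22 * 200 + 0.08 * 800 + 0.07 * 3000
  expect_equal(asmr(r5, w5), hand, tolerance = 1e-9)
  expect_error(asmr(c(young = 1), w), "missing age stratum")
  expect_error(asmr(c(young = 1, old = 2),
                    dplyr::mutate(w, weight = c(0.6, 0.6))), "sum to 1")
})

test_that("asmr is invariant to rescaling all populations", {
  # rates computed from counts/population are unchanged when populations
  # and counts scale together
  w <- tibble::tibble(age_group = c("a", "b"), weight = c(0.3, 0.7))
  pop <- c(a = 1000, b = 2000)
  deaths <- c(a = 5, b = 40)
  r1 <- asmr(deaths / pop, w)
  r2 <- asmr((deaths * 10) / (pop * 10), w)
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("AAPC matches its closed forms and scale invariance", {
  expect_equal(aapc(rep(100, 5), 2006:2010), 0)
  expect_equal(aapc(100 * 0.99^(0:9), 2006:2015), -1, tolerance = 1e-9)
  # regression and endpoint agree on geometric series
  g <- 250 * 0.985^(0:14)
  expect_equal(aapc(g, 2006:2020),
               aapc(g, 2006:2020, method = "endpoint"), tolerance = 1e-9)
  # invariant to multiplying the series by a constant
  set.seed(9)
  noisy <- 200 * 0.99^(0:14) * exp(stats::rnorm(15, 0, 0.02))
  expect_equal(aapc(noisy, 2006:2020), aapc(noisy * 3.7, 2006:2020),
               tolerance = 1e-9)
  expect_error(aapc(c(100, -1), 2006:2007), "positive")
  expect_error(aapc(100, 2006), "at least 2")
})
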