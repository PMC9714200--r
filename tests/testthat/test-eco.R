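test_that("imputation is the identity on complete tables and errors sensibly", {
  g <- make_lattice(4, 4)
  x <- simulate_covariates(g, seed = 2)
  out <- impute_covariates(x, m = 3, seed = 1)
  expect_length(out, 3)
  for (tab in out) expect_equal(tab, x)
  expect_error(impute_covariates(x, m = 0), "positive integer")
  x2 <- x
  x2$GDP[1:10] <- NA # 10 of 16: under 50% observed
  expect_error(impute_covariates(x2, m = 2), "50%")
})

test_that("masked values are recovered near their truth by chained PMM", {
  g <- make_lattice(8, 8)
  x <- simulate_covariates(g, seed = 3)
  truth <- x$GDP[5]
  errs <- numeric(25)
  for (r in seq_len(25)) {
    x2 <- x
    x2$GDP[5] <- NA
    imp <- impute_covariates(x2, m = 2, seed = 100 + r)
    errs[r] <- mean(vapply(imp, function(t) t$GDP[5], numeric(1))) - truth
  }
  # the imputation model regresses GDP on correlated covariates (NTL etc.),
  # so the average recovered value should sit within the residual spread
  expect_lt(abs(mean(errs)), 2 * stats::sd(x$GDP))
  # draws vary across seeds (it is a proper stochastic imputation)
  expect_gt(stats::sd(errs), 0)
})

test_that("covariate standardization is invertible and validates input", {
  g <- make_lattice(4, 4)
  x <- simulate_covariates(g, seed = 4)
  sx <- standardize_covariates(x)
  scaling <- attr(sx, "scaling")
  # round-trip confounders through the recorded centers and scales
  for (cn in c("TEMP", "HUMID", "PM25")) {
    back <- sx[[cn]] * scaling[[cn]]$scale + scaling[[cn]]$center
    expect_equal(back, x[[cn]], tolerance = 1e-12)
  }
  # focal covariates keep their units by default
  expect_equal(sx$GDP, x$GDP)
  # divisor support: coefficients per 10-unit change
  sx2 <- standardize_covariates(x, focal_divisors = c(GDP = 10))
  expect_equal(sx2$GDP, x$GDP / 10)
  x$NB <- 5
  expect_error(standardize_covariates(x), "zero-variance")
})

test_that("a z-scored covariate rescales its coefficient by the sd", {
  # fitted on a Poisson toy: beta on z-scored x equals raw beta times sd(x)
  set.seed(5)
  n <- 400
  x <- stats::rnorm(n, 10, 3)
  y <- stats::rpois(n, exp(1 + 0.08 * x))
  raw <- stats::glm(y ~ x, family = stats::poisson())
  zs <- stats::glm(y ~ scale(x), family = stats::poisson())
  expect_equal(unname(stats::coef(zs)[2]),
               unname(stats::coef(raw)[2]) * stats::sd(x), tolerance = 1e-6)
})

test_that("relative-risk summaries match quantiles of the draws", {
  # all draws at ln(0.89): an 11% decrease with certainty
  const <- rep(log(0.89), 200)
  eff <- rr_summary(const, "NTL")
  expect_equal(eff$rr, 0.89)
  expect_equal(eff$pct_decrease, 11)
  expect_equal(eff$prob_protective, 1)
  # all-zero draws: null effect, probability reported 0.5 by symmetry
  eff0 <- rr_summary(rep(0, 200), "NB")
  expect_equal(eff0$rr, 1)
  expect_equal(eff0$pct_decrease, 0)
  expect_equal(eff0$prob_protective, 0.5)
  # normal draws: summaries equal direct quantiles of the same sample
  set.seed(6)
  dr <- stats::rnorm(1000, log(0.9), 0.05)
  eff2 <- rr_summary(dr, "GDP")
  q <- stats::quantile(exp(dr), c(0.025, 0.5, 0.975), names = FALSE)
  expect_equal(c(eff2$rr_lo, eff2$rr, eff2$rr_hi), q)
  expect_equal(eff2$prob_protective, mean(dr < 0))
  expect_error(rr_summary(numeric(0)), "empty")
})

test_that("regional fits cover planted region-specific effects", {
  # NTL protective only in the eastern tertile; the eastern fit should
  # find it with high protective probability while remaining region-sized
  cfg <- sim_config(n_rows = 6, n_cols = 6, years = 2006:2013, seed = 71,
                    beta = c(NTL = log(0.75)))
  g <- make_lattice(6, 6)
  covs <- simulate_covariates(g, seed = 72)
  # zero the effect outside the east by flattening NTL there
  truth_covs <- covs
  truth_covs$NTL[g$nodes$region != "eastern"] <-
    mean(covs$NTL[g$nodes$region != "eastern"])
  truth <- simulate_truth(g, cfg, covariates = truth_covs, seed = 71)
  template <- make_panel_template(g, cfg, seed = 73)
  panel <- simulate_counts(truth, template, seed = 74)
  spec <- hbstm_spec(covariates = "NTL", effects = c("s", "u", "eps"))
  eff <- fit_regional(panel, g, covs, spec,
                      iterations = 900, burn_in = 300, thin = 2, seed = 75)
  east <- eff[eff$region == "eastern" & eff$covariate == "NTL", ]
  expect_gt(east$prob_protective, 0.8)
  expect_true(all(c("nationwide", "eastern", "central", "western")
                  %in% eff$region))
  # small regions are skipped with a warning
  expect_warning(
    fit_regional(panel, g, covs, spec,
                 regions = tibble::tibble(
                   county_id = g$nodes$county_id,
                   region = c("tiny", rep("rest", 35))
                 ),
                 iterations = 300, burn_in = 100, seed = 76),
    "fewer than"
  )
})

test_that("pooled imputation intervals are no narrower than single-table ones", {
  # direct check of the pooling mechanics on constructed draws
  set.seed(7)
  d1 <- stats::rnorm(400, log(0.9), 0.04)
  d2 <- stats::rnorm(400, log(0.95), 0.04) # between-imputation shift
  single1 <- rr_summary(d1)
  single2 <- rr_summary(d2)
  pooled <- rr_summary(c(d1, d2))
  w <- function(e) e$rr_hi - e$rr_lo
  expect_gte(w(pooled), min(w(single1), w(single2)))
  expect_gt(w(pooled), 0.95 * mean(c(w(single1), w(single2))))
})

test_that("an irrelevant confounder barely moves the focal relative risks", {
  truebeta <- c(NTL = log(0.85))
  cfg <- sim_config(n_rows = 6, n_cols = 6, years = 2006:2011, seed = 96,
                    beta = truebeta)
  g <- make_lattice(6, 6)
  covs <- simulate_covariates(g, seed = 97)
  set.seed(98)
  covs$noise_conf <- stats::rnorm(nrow(covs)) # unrelated to outcome and NTL
  truth <- simulate_truth(g, cfg, covariates = covs, seed = 96)
  template <- make_panel_template(g, cfg, seed = 99)
  panel <- simulate_counts(truth, template, seed = 100)
  expct <- dplyr::summarise(
    dplyr::group_by(panel, .data$county_id, .data$year),
    expected = sum(.data$e_cvd), .groups = "drop"
  )
  base <- fit_hbstm(panel, g, expected = expct, covariates = covs,
                    spec = hbstm_spec(covariates = "NTL",
                                      effects = c("s", "u", "eps")),
                    iterations = 900, burn_in = 300, thin = 2, seed = 101)
  adj <- fit_hbstm(panel, g, expected = expct, covariates = covs,
                   spec = hbstm_spec(covariates = "NTL",
                                     confounders = "noise_conf",
                                     effects = c("s", "u", "eps")),
                   iterations = 900, burn_in = 300, thin = 2, seed = 101)
  b_base <- base$draws$beta[, "NTL"]
  b_adj <- adj$draws$beta[, "NTL"]
  expect_lt(abs(stats::median(b_base) - stats::median(b_adj)),
            stats::sd(b_base))
})
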