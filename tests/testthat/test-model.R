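# Brute-force Poisson log-likelihood: an explicit loop over cells, kept
# deliberately independent of the vectorised implementation.
brute_poisson_ll <- function(Y, E, eta) {
  total <- 0
  for (i in seq_len(nrow(Y))) {
    for (j in seq_len(ncol(Y))) {
      total <- total + Y[i, j] * eta[i, j] - E[i, j] * exp(eta[i, j])
    }
  }
  total
}

random_state <- function(n, Tn, graph) {
  list(
    alpha = stats::rnorm(1), b0 = stats::rnorm(1, 0, 0.1),
    s = stats::rnorm(n, 0, 0.3), u = stats::rnorm(n, 0, 0.2),
    v = stats::rnorm(Tn, 0, 0.1), b1 = stats::rnorm(n, 0, 0.05),
    eps = matrix(stats::rnorm(n * Tn, 0, 0.1), n, Tn),
    tau_s = stats::rgamma(1, 2, 1), tau_u = stats::rgamma(1, 2, 1),
    tau_v = stats::rgamma(1, 2, 1), tau_b1 = stats::rgamma(1, 2, 1),
    tau_eps = stats::rgamma(1, 2, 1)
  )
}

test_that("the Poisson term of the log-posterior matches a brute-force loop", {
  set.seed(11)
  for (rep in 1:100) {
    n <- sample(1:4, 1)
    Tn <- sample(1:5, 1)
    while (n * Tn > 20) Tn <- sample(1:5, 1)
    g <- make_lattice(n, 1)
    Y <- matrix(stats::rpois(n * Tn, 5), n, Tn)
    E <- matrix(stats::runif(n * Tn, 0.5, 10), n, Tn)
    st <- random_state(n, Tn, g)
    t <- seq_len(Tn) - (Tn + 1) / 2
    parts <- log_posterior(st, Y, E, graph = g, t = t, parts = TRUE)
    eta <- st$alpha + st$s + st$u + st$eps +
      outer(rep(1, n), st$b0 * t + st$v) + outer(st$b1, t)
    expect_equal(unname(parts["loglik"]), brute_poisson_ll(Y, E, eta),
                 tolerance = 1e-10)
  }
})

test_that("single-cell likelihood term equals direct substitution", {
  # Y = 3, E = 2, eta = 0: term is 3*0 - 2*1 = -2
  g <- make_lattice(1, 1)
  st <- list(alpha = 0, tau_s = 1, tau_u = 1, tau_v = 1, tau_b1 = 1,
             tau_eps = 1)
  parts <- log_posterior(st, matrix(3), matrix(2), graph = g,
                         spec = hbstm_spec(effects = character(0)),
                         parts = TRUE)
  expect_equal(unname(parts["loglik"]), -2)
})

test_that("changing a variance at zeroed effects only moves the hyperprior", {
  g <- make_lattice(2, 2)
  Y <- matrix(stats::rpois(8, 4), 4, 2)
  E <- matrix(2, 4, 2)
  base <- list(alpha = 0.1, b0 = 0, s = numeric(4), u = numeric(4),
               v = numeric(2), b1 = numeric(4), eps = matrix(0, 4, 2),
               tau_s = 1, tau_u = 1, tau_v = 1, tau_b1 = 1, tau_eps = 1)
  doubled <- base
  doubled$tau_eps <- 0.5
  p1 <- log_posterior(base, Y, E, graph = g, parts = TRUE)
  p2 <- log_posterior(doubled, Y, E, graph = g, parts = TRUE)
  moved <- names(p1)[abs(p1 - p2) > 1e-12]
  expect_setequal(moved, c("eps", "tau_eps"))
})

test_that("icar log-density matches hand computations", {
  g2 <- county_graph(tibble::tibble(county_id = c("a", "b")),
                     tibble::tibble(from = "a", to = "b"))
  # constant vector: pairwise term vanishes, only the rank term remains
  expect_equal(icar_logdensity(c(3, 3), g2, tau = 2),
               (2 - 1) / 2 * log(2))
  # x = (1, -1), tau = 1: -(1/2)*(1-(-1))^2 = -2 plus rank term 0
  expect_equal(icar_logdensity(c(1, -1), g2, tau = 1), -2)
  # translation invariance
  g <- make_lattice(3, 3)
  set.seed(12)
  x <- stats::rnorm(9)
  expect_equal(icar_logdensity(x, g, 1.7),
               icar_logdensity(x + 5, g, 1.7), tolerance = 1e-9)
  expect_error(icar_logdensity(x[1:5], g, 1), "one value per county")
  expect_error(icar_logdensity(x, g, 0), "positive")
})

test_that("expected counts satisfy the SMR identity and conservation", {
  panel <- two_county_panel()
  ec <- expected_counts(panel)
  # conservation under the internal reference
  expect_equal(sum(ec$expected), sum(ec$observed), tolerance = 1e-9)
  # hand computation: pooled young rate = (2+3+4+5)/4000? no - by age over
  # all counties and years
  young_rate <- (2 + 3 + 4 + 5) / (1000 + 1000 + 2000 + 2000)
  old_rate <- (10 + 12 + 20 + 24) / (500 + 500 + 1000 + 1000)
  e_a_2006 <- 1000 * young_rate + 500 * old_rate
  expect_equal(ec$expected[ec$county_id == "a" & ec$year == 2006], e_a_2006)
  # a county whose stratum rates equal the reference has SMR 1 every year
  ref <- tibble::tibble(age_group = c("young", "old"), rate = c(0.002, 0.02))
  p2 <- tibble::tibble(
    county_id = "z", year = rep(2006:2008, each = 2),
    age_group = rep(c("young", "old"), 3),
    population = rep(c(5000, 1000), 3),
    deaths_cvd = rep(c(10, 20), 3)
  )
  ec2 <- expected_counts(p2, reference = ref)
  expect_equal(ec2$observed / ec2$expected, rep(1, 3))
  expect_error(
    expected_counts(dplyr::mutate(panel, deaths_cvd = 0)),
    "non-zero death total"
  )
})

test_that("a single-cell fit reproduces the conjugate gamma posterior", {
  # one county, one year, no random effects, flat prior on alpha:
  # posterior of exp(alpha) is Gamma(Y, E)
  g <- make_lattice(1, 1)
  Yobs <- 30
  Eexp <- 10
  panel <- tibble::tibble(county_id = "c0001", year = 2006L,
                          population = 1000, deaths_cvd = Yobs)
  expected <- tibble::tibble(county_id = "c0001", year = 2006L,
                             expected = Eexp)
  fit <- fit_hbstm(panel, g, expected = expected,
                   spec = hbstm_spec(effects = character(0)),
                   iterations = 4000, burn_in = 500, thin = 1, seed = 21)
  draws <- exp(fit$draws$alpha)
  # exact Gamma(30, 10): mean 3; draws are iid (Gibbs), so the MC standard
  # error is sd/sqrt(n)
  mc_se <- stats::sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - Yobs / Eexp), 3 * mc_se)
  # compare full distribution against the closed form
  ks <- stats::ks.test(draws, stats::pgamma, shape = Yobs, rate = Eexp)
  expect_gt(ks$p.value, 0.001)
})

test_that("fits are deterministic given the seed", {
  sim <- simulate_panel(tiny_config(seed = 5))
  f1 <- fit_hbstm(sim$panel, sim$graph, iterations = 300, burn_in = 100,
                  thin = 1, seed = 7)
  f2 <- fit_hbstm(sim$panel, sim$graph, iterations = 300, burn_in = 100,
                  thin = 1, seed = 7)
  expect_identical(f1$draws$alpha, f2$draws$alpha)
  expect_identical(f1$draws$s, f2$draws$s)
})

test_that("posterior SMR of an outlier county is shrunk toward its neighbors", {
  # one high-rate county among low-rate neighbors on a lattice
  g <- make_lattice(4, 4)
  ids <- g$nodes$county_id
  set.seed(30)
  E <- 60
  hot <- "c0006" # interior county
  panel <- tidyr::expand_grid(county_id = ids, year = 2006:2010)
  panel$population <- 1e5
  rate <- ifelse(panel$county_id == hot, 2.0, 1.0)
  panel$deaths_cvd <- stats::rpois(nrow(panel), E * rate)
  expected <- tidyr::expand_grid(county_id = ids, year = 2006:2010)
  expected$expected <- E
  fit <- fit_hbstm(panel, g, expected = expected,
                   spec = hbstm_spec(effects = c("s", "u")),
                   iterations = 1500, burn_in = 500, thin = 2, seed = 31)
  th <- theta_draws(fit)
  smr_fit <- mean(th[, hot, ])
  smr_raw <- sum(panel$deaths_cvd[panel$county_id == hot]) / (5 * E)
  neighbor_mean <- 1.0
  expect_lt(smr_fit, smr_raw)
  expect_gt(smr_fit, neighbor_mean)
})

test_that("per-draw centering of s, v and b1 holds", {
  sim <- simulate_panel(tiny_config(seed = 6))
  fit <- fit_hbstm(sim$panel, sim$graph, iterations = 400, burn_in = 200,
                   thin = 1, seed = 8)
  expect_lt(max(abs(rowMeans(fit$draws$s))), 1e-8)
  expect_lt(max(abs(rowMeans(fit$draws$v))), 1e-8)
  expect_lt(max(abs(rowMeans(fit$draws$b1))), 1e-8)
})

test_that("tight hyperpriors collapse the posterior toward the pooled SMR", {
  # with all random-effect variances forced near zero the fitted risks
  # approach sum(Y)/sum(E) uniformly
  sim <- simulate_panel(tiny_config(seed = 9))
  spec <- hbstm_spec(prec_shape = 5000, prec_rate = 0.05) # E[tau] = 1e5
  fit <- fit_hbstm(sim$panel, sim$graph, spec = spec,
                   iterations = 800, burn_in = 300, thin = 1, seed = 10)
  ec <- expected_counts(sim$panel)
  pooled <- sum(ec$observed) / sum(ec$expected)
  th <- theta_draws(fit)
  post_mean <- apply(th, c(2, 3), mean)
  expect_lt(max(abs(post_mean - pooled)), 0.15)
})

test_that("information criteria detect structure and degenerate posteriors", {
  sim <- simulate_panel(tiny_config(seed = 13))
  fit <- fit_hbstm(sim$panel, sim$graph, iterations = 500, burn_in = 200,
                   thin = 1, seed = 14)
  ic <- information_criterion(fit)
  expect_true(ic$p_waic > 0)
  expect_true(is.finite(ic$dic))
  # degenerate: a fit whose draws are all identical has zero effective
  # parameters
  degen <- fit
  keep <- function(m) m[rep(1, 60), , drop = FALSE]
  degen$draws$alpha <- rep(fit$draws$alpha[1], 60)
  degen$draws$b0 <- rep(fit$draws$b0[1], 60)
  degen$draws$beta <- fit$draws$beta[rep(1, 60), , drop = FALSE]
  degen$draws$s <- keep(fit$draws$s)
  degen$draws$u <- keep(fit$draws$u)
  degen$draws$v <- keep(fit$draws$v)
  degen$draws$b1 <- keep(fit$draws$b1)
  degen$draws$eps <- keep(fit$draws$eps)
  ic0 <- information_criterion(degen)
  expect_equal(ic0$p_waic, 0, tolerance = 1e-8)
  expect_equal(ic0$p_dic, 0, tolerance = 1e-6)
  short <- fit
  short$draws$alpha <- short$draws$alpha[1:10]
  expect_error(information_criterion(short), "at least 50")
})

test_that("information criteria prefer the covariate model on structured data", {
  # The comparison is only informative when the fitted random effects
  # cannot fully absorb the covariate signal: a time-fixed X*beta is
  # perfectly collinear with an exchangeable county effect u, so both fits
  # here carry only the CAR field (which cannot mimic the covariates'
  # non-smooth component) and the cell noise.
  truebeta <- c(GDP = log(0.6), NTL = log(0.75))
  cfg <- sim_config(n_rows = 6, n_cols = 6, years = 2006:2012, seed = 391,
                    beta = truebeta, sd_s = 0.1, sd_u = 0, sd_eps = 0.02)
  g <- make_lattice(6, 6)
  covs <- simulate_covariates(g, seed = 392)
  truth <- simulate_truth(g, cfg, covariates = covs, seed = 391)
  template <- make_panel_template(g, cfg, seed = 393)
  panel <- simulate_counts(truth, template, seed = 394)
  expct <- dplyr::summarise(
    dplyr::group_by(panel, .data$county_id, .data$year),
    expected = sum(.data$e_cvd), .groups = "drop"
  )
  fit_null <- fit_hbstm(panel, g, expected = expct,
                        spec = hbstm_spec(effects = c("s", "eps")),
                        iterations = 900, burn_in = 300, thin = 2, seed = 395)
  fit_cov <- fit_hbstm(panel, g, expected = expct, covariates = covs,
                       spec = hbstm_spec(covariates = c("GDP", "NTL"),
                                         effects = c("s", "eps")),
                       iterations = 900, burn_in = 300, thin = 2, seed = 395)
  ic_null <- information_criterion(fit_null)
  ic_cov <- information_criterion(fit_cov)
  expect_lt(ic_cov$waic, ic_null$waic)
  expect_lt(ic_cov$dic, ic_null$dic)
})
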