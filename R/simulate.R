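#' Configuration for the synthetic county generator
#'
#' Bundles every knob of the generative process the spatiotemporal model
#' assumes: a rook-adjacency lattice of counties, a 15-year annual panel,
#' two sexes by five age bands with multiplicative age-sex reference rates,
#' BYM spatial effects (structured CAR + unstructured), a global linear trend
#' with exchangeable nonlinear deviations, CAR-correlated local slopes,
#' i.i.d. space-time noise, optional county-level covariate effects, and
#' binomial under-reporting by stratum-year.
#'
#' Standard deviations are on the log-risk scale. The default global slope
#' `b0 = -0.012` corresponds to roughly a -1.2% annual change in risk, the
#' order of magnitude seen in national cardiovascular mortality trends; the
#' spatial scale `sd_s = 0.3` produces county relative risks spanning about
#' 0.4-2.5, comparable to published county maps.
#'
#' @param n_rows,n_cols Lattice dimensions (default 10 x 10 counties).
#' @param years Calendar years of the panel (default 2006-2020).
#' @param sexes,age_groups Stratum labels.
#' @param age_shares Population share per age band (sums to 1).
#' @param cvd_rates Reference CVD mortality rate per person-year, one per
#'   age band, before the sex multiplier.
#' @param sex_multipliers Named multiplicative factors on the reference
#'   rates, one per sex.
#' @param cvd_share CVD share of all-cause deaths, used to set the
#'   non-CVD reference rate (all-cause = CVD / share).
#' @param pop_range County population drawn uniformly from this range.
#' @param alpha Log baseline relative risk.
#' @param b0 Global linear trend per year on the log scale.
#' @param sd_s,sd_u,sd_v,sd_b1,sd_eps Standard deviations of the structured
#'   spatial effect, unstructured spatial effect, nonlinear yearly trend
#'   deviations, CAR local slopes, and space-time noise.
#' @param beta Optional named vector of covariate coefficients (log-RR per
#'   model unit); names must match columns of the covariate table.
#' @param urr Optional under-reporting schedule (see
#'   [default_urr_schedule()]); `NULL` uses the default declining schedule.
#' @param seed Integer seed; the seed fully determines all output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_rows = 10, n_cols = 10,
                       years = 2006:2020,
                       sexes = c("female", "male"),
                       age_groups = c("0-14", "15-44", "45-64", "65-74", "75+"),
                       age_shares = c(0.18, 0.45, 0.22, 0.08, 0.07),
                       cvd_rates = c(2, 20, 200, 800, 3000) / 1e5,
                       sex_multipliers = c(female = 0.87, male = 1.13),
                       cvd_share = 0.40,
                       pop_range = c(2e4, 2e5),
                       alpha = 0, b0 = -0.012,
                       sd_s = 0.3, sd_u = 0.1, sd_v = 0.02,
                       sd_b1 = 0.01, sd_eps = 0.05,
                       beta = NULL, urr = NULL, seed = 1L) {
  stopifnot(
    length(years) >= 2,
    length(age_shares) == length(age_groups),
    abs(sum(age_shares) - 1) < 1e-8,
    length(cvd_rates) == length(age_groups),
    all(pop_range > 0), length(pop_range) == 2,
    all(c(sd_s, sd_u, sd_v, sd_b1, sd_eps) >= 0),
    cvd_share > 0, cvd_share <= 1
  )
  if (!is.null(beta) && is.null(names(beta))) {
    stop("beta must be a named vector of covariate coefficients", call. = FALSE)
  }
  structure(
    list(
      n_rows = n_rows, n_cols = n_cols, years = as.integer(years),
      sexes = sexes, age_groups = age_groups, age_shares = age_shares,
      cvd_rates = cvd_rates, sex_multipliers = sex_multipliers,
      cvd_share = cvd_share, pop_range = pop_range,
      alpha = alpha, b0 = b0,
      sd_s = sd_s, sd_u = sd_u, sd_v = sd_v, sd_b1 = sd_b1, sd_eps = sd_eps,
      beta = beta, urr = urr, seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# Centered year index used throughout: mid-period year maps to 0, so the
# intercept is the mid-period log-risk and is decorrelated from the slope.
year_index <- function(years) years - (min(years) + max(years)) / 2

#' Draw from the intrinsic CAR distribution on a graph
#'
#' Samples the rank-deficient intrinsic CAR prior exactly by drawing
#' independent normals on the positive-eigenvalue subspace of the graph
#' Laplacian (variance `sd^2 / lambda_k` per eigendirection) and rotating
#' back. The null space (one constant mode per connected component) carries
#' no mass, so the draw sums to zero within every component by construction;
#' a final centering removes residual floating-point drift.
#'
#' @param graph A `county_graph`.
#' @param sd Marginal scale parameter (the CAR standard deviation); `0`
#'   returns the zero vector.
#' @return A numeric vector in node order with mean zero.
#' @export
ricar <- function(graph, sd) {
  n <- n_counties(graph)
  if (sd == 0 || n == 1) return(numeric(n))
  comp <- graph_components(graph)
  if (comp$n > 1) {
    warning("graph is disconnected (", comp$n,
            " components); CAR draw proceeds per component", call. = FALSE)
  }
  L <- as.matrix(laplacian_matrix(graph))
  eig <- eigen(L, symmetric = TRUE)
  pos <- eig$values > max(eig$values) * 1e-10
  z <- stats::rnorm(sum(pos), sd = sd / sqrt(eig$values[pos]))
  x <- as.numeric(eig$vectors[, pos, drop = FALSE] %*% z)
  x - mean(x)
}

#' Simulate the true risk surface
#'
#' Draws every component of the log-linear risk decomposition
#' `log(theta_it) = alpha + s_i + u_i + b0 t + v_t + b1_i t + eps_it (+ X beta)`:
#' `s` and `b1` from the intrinsic CAR prior on the supplied graph, `u` and
#' `eps` i.i.d. Gaussian, `v` Gaussian then centered. Setting a standard
#' deviation to zero makes that component exactly zero.
#'
#' @param graph A `county_graph`.
#' @param config A [sim_config()].
#' @param covariates Optional county-level covariate tibble (one row per
#'   county in node order, columns matching `names(config$beta)`); the
#'   covariate contribution is computed on mean-centered columns so the
#'   baseline `alpha` keeps its interpretation.
#' @param seed Seed; defaults to `config$seed`.
#' @return A `truth_surface` list with elements `alpha`, `b0`, `s`, `u`,
#'   `v`, `b1`, `eps` (county x year matrix), `beta`, `xbeta` (per-county
#'   covariate contribution) and the year/county labels.
#' @export
simulate_truth <- function(graph, config, covariates = NULL,
                           seed = config$seed) {
  stopifnot(inherits(graph, "county_graph"), inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- n_counties(graph)
  yrs <- config$years
  T <- length(yrs)
  s <- ricar(graph, config$sd_s)
  u <- stats::rnorm(n, 0, config$sd_u)
  v <- stats::rnorm(T, 0, config$sd_v)
  v <- v - mean(v)
  b1 <- ricar(graph, config$sd_b1)
  eps <- matrix(stats::rnorm(n * T, 0, config$sd_eps), n, T)
  xbeta <- numeric(n)
  if (!is.null(config$beta)) {
    if (is.null(covariates)) {
      stop("config$beta is set but no covariates were supplied", call. = FALSE)
    }
    miss <- setdiff(names(config$beta), names(covariates))
    if (length(miss)) {
      stop("covariate columns missing: ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    X <- as.matrix(covariates[match(graph$nodes$county_id, covariates$county_id),
                              names(config$beta)])
    X <- scale(X, center = TRUE, scale = FALSE)
    xbeta <- as.numeric(X %*% config$beta)
  }
  structure(
    list(
      alpha = config$alpha, b0 = config$b0,
      s = s, u = u, v = v, b1 = b1, eps = eps,
      beta = config$beta, xbeta = xbeta,
      county_id = graph$nodes$county_id, years = yrs,
      sd = c(s = config$sd_s, u = config$sd_u, v = config$sd_v,
             b1 = config$sd_b1, eps = config$sd_eps)
    ),
    class = "truth_surface"
  )
}

# True relative risk theta_it as a county x year matrix.
truth_theta <- function(truth) {
  tv <- year_index(truth$years)
  eta <- truth$alpha + truth$xbeta + truth$s + truth$u +
    outer(rep(1, length(truth$s)), truth$b0 * tv + truth$v) +
    outer(truth$b1, tv) + truth$eps
  exp(eta)
}

#' Panel template with populations and expected counts
#'
#' Expands a county graph into the county x year x sex x age cell grid,
#' draws county populations uniformly from `config$pop_range`, splits them
#' by the configured age shares and an even sex split, and attaches the
#' expected CVD and non-CVD death counts implied by the multiplicative
#' age-sex reference rates. Because the reference rates are shared by all
#' counties, expected counts can later be reconstructed from the panel alone
#' by indirect standardization.
#'
#' @inheritParams simulate_truth
#' @return A tibble with columns `county_id`, `region`, `urban`, `year`,
#'   `sex`, `age_group`, `population`, `e_cvd`, `e_other`.
#' @export
make_panel_template <- function(graph, config, seed = config$seed + 1L) {
  stopifnot(inherits(graph, "county_graph"), inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- n_counties(graph)
  pop_total <- stats::runif(n, config$pop_range[1], config$pop_range[2])
  nodes <- graph$nodes
  if (is.null(nodes$region)) nodes$region <- "eastern"
  if (is.null(nodes$urban)) nodes$urban <- FALSE
  cells <- tidyr::expand_grid(
    county_id = nodes$county_id,
    year = config$years,
    sex = config$sexes,
    age_group = config$age_groups
  )
  rate_tab <- tidyr::expand_grid(
    sex = config$sexes, age_group = config$age_groups
  )
  rate_tab$rate_cvd <- config$cvd_rates[match(rate_tab$age_group, config$age_groups)] *
    config$sex_multipliers[rate_tab$sex]
  rate_tab$rate_other <- rate_tab$rate_cvd * (1 - config$cvd_share) / config$cvd_share
  cells <- dplyr::left_join(cells, rate_tab, by = c("sex", "age_group"))
  cells$population <- round(
    pop_total[match(cells$county_id, nodes$county_id)] *
      config$age_shares[match(cells$age_group, config$age_groups)] /
      length(config$sexes)
  )
  cells$e_cvd <- cells$population * cells$rate_cvd
  cells$e_other <- cells$population * cells$rate_other
  cells$region <- nodes$region[match(cells$county_id, nodes$county_id)]
  cells$urban <- nodes$urban[match(cells$county_id, nodes$county_id)]
  dplyr::select(cells, "county_id", "region", "urban", "year", "sex",
                "age_group", "population", "e_cvd", "e_other")
}

#' Simulate death counts from a true risk surface
#'
#' Draws `Y ~ Poisson(E * theta_it)` cell-wise, where `theta_it` is the true
#' county-year relative risk and `E` the cell's expected CVD count from the
#' template; non-CVD deaths are drawn around their own expectation with no
#' spatial structure, so `deaths_all = deaths_cvd + deaths_other`. The true
#' `theta_it` is attached as the attribute `"theta"` for recovery tests.
#'
#' @param truth A `truth_surface`.
#' @param template A panel template (from [make_panel_template()] or any
#'   tibble with `county_id`, `year`, `population` and positive `e_cvd`;
#'   `sex`/`age_group`/`e_other` are optional).
#' @param seed Seed (`NULL` continues the current RNG stream).
#' @return A `CountyPanel` tibble with `deaths_cvd` and `deaths_all` counts
#'   and an attached `"theta"` tibble of true relative risks.
#' @export
simulate_counts <- function(truth, template, seed = NULL) {
  stopifnot(inherits(truth, "truth_surface"))
  if (!is.null(seed)) set.seed(seed)
  if (any(!is.finite(template$e_cvd)) || any(template$e_cvd <= 0)) {
    bad <- which(!is.finite(template$e_cvd) | template$e_cvd <= 0)[1]
    stop("expected counts must be positive and finite; offending cell: ",
         template$county_id[bad], " / ", template$year[bad], call. = FALSE)
  }
  theta <- truth_theta(truth)
  if (any(!is.finite(theta))) {
    bad <- which(!is.finite(theta), arr.ind = TRUE)[1, ]
    stop("non-finite linear predictor at county ", truth$county_id[bad[1]],
         ", year ", truth$years[bad[2]], call. = FALSE)
  }
  i <- match(template$county_id, truth$county_id)
  t <- match(template$year, truth$years)
  if (anyNA(i) || anyNA(t)) {
    stop("template contains counties or years absent from the truth surface",
         call. = FALSE)
  }
  th <- theta[cbind(i, t)]
  panel <- tibble::as_tibble(template)
  panel$deaths_cvd <- stats::rpois(nrow(panel), panel$e_cvd * th)
  other <- if ("e_other" %in% names(panel)) {
    stats::rpois(nrow(panel), panel$e_other)
  } else 0L
  panel$deaths_all <- panel$deaths_cvd + other
  over <- panel$deaths_all > panel$population
  if (any(over)) {
    panel$deaths_all[over] <- panel$population[over]
    panel$deaths_cvd[over] <- pmin(panel$deaths_cvd[over], panel$deaths_all[over])
  }
  panel <- panel[setdiff(names(panel), c("e_other", "rate_cvd", "rate_other"))]
  attr(panel, "theta") <- tibble::tibble(
    county_id = rep(truth$county_id, times = length(truth$years)),
    year = rep(truth$years, each = length(truth$county_id)),
    theta_true = as.numeric(theta)
  )
  panel
}

#' Default under-reporting schedule
#'
#' A plausible stratum-year schedule for synthetic studies: under-reporting
#' is higher in rural and western strata and declines by one percentage
#' point per year from the first year, floored at 2%. Values stay well
#' inside \code{[0, 0.95]}.
#'
#' @param years Calendar years to cover.
#' @return A tibble with columns `region`, `urban`, `year`, `urr`.
#' @export
default_urr_schedule <- function(years = 2006:2020) {
  base <- tidyr::expand_grid(
    region = c("eastern", "central", "western"),
    urban = c(TRUE, FALSE)
  )
  base$urr0 <- c(0.12, 0.20, 0.18, 0.25, 0.22, 0.30)
  out <- tidyr::expand_grid(base, year = as.integer(years))
  out$urr <- pmax(0.02, out$urr0 - 0.01 * (out$year - min(years)))
  dplyr::select(out, "region", "urban", "year", "urr")
}

#' Thin a panel by binomial under-reporting
#'
#' Applies the registry's missingness generatively: each death is reported
#' independently with probability `1 - URR` for its stratum-year, so
#' `deaths_cvd_reported ~ Binomial(deaths_cvd, 1 - URR)` (and likewise for
#' non-CVD deaths, summed into `deaths_all_reported`). True counts are
#' retained so adjustment can be checked against them.
#'
#' @param panel A `CountyPanel` with `region` and `urban` columns (or pass a
#'   `strata` table mapping `county_id` to them).
#' @param urr_schedule Tibble with `region`, `urban`, `year`, `urr`.
#' @param strata Optional tibble `county_id`, `region`, `urban` used when the
#'   panel lacks those columns.
#' @param seed Seed (`NULL` continues the current RNG stream).
#' @return The panel with `deaths_cvd_reported` and `deaths_all_reported`
#'   columns appended.
#' @export
apply_underreporting <- function(panel, urr_schedule, strata = NULL,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  panel <- tibble::as_tibble(panel)
  if (!all(c("region", "urban") %in% names(panel))) {
    if (is.null(strata)) {
      stop("panel lacks region/urban columns and no strata table supplied",
           call. = FALSE)
    }
    panel <- dplyr::left_join(panel, strata, by = "county_id")
  }
  key <- dplyr::left_join(
    panel[, c("region", "urban", "year")],
    urr_schedule, by = c("region", "urban", "year")
  )
  if (anyNA(key$urr)) {
    miss <- unique(key[is.na(key$urr), c("region", "urban", "year")])
    stop("URR schedule missing for stratum-years: ",
         paste(sprintf("%s/%s/%d", miss$region,
                       ifelse(miss$urban, "urban", "rural"), miss$year),
               collapse = "; "),
         call. = FALSE)
  }
  if (any(key$urr < 0 | key$urr >= 1)) {
    stop("URR values must lie in [0, 1)", call. = FALSE)
  }
  p <- 1 - key$urr
  panel$deaths_cvd_reported <- stats::rbinom(nrow(panel), panel$deaths_cvd, p)
  other <- panel$deaths_all - panel$deaths_cvd
  panel$deaths_all_reported <- panel$deaths_cvd_reported +
    stats::rbinom(nrow(panel), other, p)
  panel
}

#' Simulate a complete synthetic county study
#'
#' End-to-end generator: lattice geography, true risk surface, county-level
#' covariates, populations, Poisson death counts, and binomially
#' under-reported observations, all determined by `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A `county_sim` list with elements `graph`, `truth`, `covariates`,
#'   `panel` (including reported counts), `urr`, `weights` (census-style age
#'   weights used for direct standardization) and `config`.
#' @export
simulate_panel <- function(config = sim_config()) {
  graph <- make_lattice(config$n_rows, config$n_cols)
  covariates <- simulate_covariates(graph, seed = config$seed + 2L)
  truth <- simulate_truth(graph, config, covariates = covariates,
                          seed = config$seed)
  template <- make_panel_template(graph, config, seed = config$seed + 1L)
  panel <- simulate_counts(truth, template, seed = config$seed + 3L)
  urr <- if (is.null(config$urr)) default_urr_schedule(config$years) else config$urr
  panel <- apply_underreporting(panel, urr, seed = config$seed + 4L)
  structure(
    list(
      graph = graph, truth = truth, covariates = covariates,
      panel = panel, urr = urr,
      weights = tibble::tibble(age_group = config$age_groups,
                               weight = config$age_shares),
      config = config
    ),
    class = "county_sim"
  )
}

#' Simulate county-level covariates
#'
#' Generates the nonmedical-determinant table used by the ecological
#' regression: GDP per capita (10,000 yuan), nighttime-light intensity
#' (NTL), hospital beds per 10,000 persons (NB), population density (PD,
#' persons/km2), and the confounders TEMP, TV, HUMID, LT, AT and PM2.5.
#' GDP and NTL rise from west to east and are mutually correlated, mimicking
#' the socioeconomic gradient the regression is meant to pick up; the
#' remainder follow smooth spatial gradients plus noise. Covariates are
#' time-fixed (one value per county).
#'
#' @param graph A `county_graph` whose nodes carry `row`/`col` (a lattice).
#' @param seed Seed.
#' @param prop_missing Proportion of cells in the focal covariates set to
#'   `NA` at random (default 0), for exercising imputation.
#' @return A tibble, one row per county in node order.
#' @export
simulate_covariates <- function(graph, seed = 1L, prop_missing = 0) {
  if (!is.null(seed)) set.seed(seed)
  nodes <- graph$nodes
  n <- nrow(nodes)
  colf <- if (!is.null(nodes$col)) nodes$col / max(nodes$col) else stats::runif(n)
  rowf <- if (!is.null(nodes$row)) nodes$row / max(nodes$row) else stats::runif(n)
  gdp <- 2 + 0.6 * colf + stats::rnorm(n, 0, 0.45)
  x <- tibble::tibble(
    county_id = nodes$county_id,
    GDP = gdp,
    NTL = 3 + 0.8 * as.numeric(scale(gdp)) + stats::rnorm(n, 0, 0.8),
    NB = 30 + 10 * colf + stats::rnorm(n, 0, 4),
    PD = exp(stats::rnorm(n, 5.5 + colf, 0.5)),
    TEMP = 14 + 8 * (rowf - 0.5) + stats::rnorm(n, 0, 1),
    TV = 8 + 2 * (0.5 - rowf) + stats::rnorm(n, 0, 1),
    HUMID = pmin(100, pmax(0, 65 + 15 * (colf - 0.5) + stats::rnorm(n, 0, 3))),
    LT = 75 + 30 * colf,
    AT = pmax(0, 3000 * pmax(0, 0.6 - colf) + stats::rnorm(n, 200, 100)),
    PM25 = 45 + 10 * (0.5 - rowf) + stats::rnorm(n, 0, 6)
  )
  if (prop_missing > 0) {
    for (cn in c("GDP", "NTL", "NB", "PD")) {
      idx <- which(stats::runif(n) < prop_missing)
      x[[cn]][idx] <- NA_real_
    }
  }
  x
}
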