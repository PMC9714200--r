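#' Model specification for the spatiotemporal Poisson model
#'
#' Describes the hierarchical Bayesian spatiotemporal model
#' `Y_it ~ Poisson(E_it * theta_it)` with
#' `log(theta_it) = alpha + s_i + u_i + b0*t + v_t + b1_i*t + eps_it (+ X beta)`:
#' which random-effect families to include, which covariate columns enter
#' the regression, and the prior settings. `s` (structured spatial) and `b1`
#' (local slopes) carry intrinsic CAR priors on the county graph; `u`, `v`
#' and `eps` are exchangeable Gaussian; `alpha` and `b0` are uniform on wide
#' bounds; random-effect scales get either a conjugate gamma prior on the
#' precision (default, enabling Gibbs updates) or a half-Gaussian prior on
#' the standard deviation.
#'
#' @param covariates Character vector of focal covariate columns.
#' @param confounders Character vector of confounder columns (enter the
#'   linear predictor identically; kept separate only for reporting).
#' @param effects Random-effect families to include, a subset of
#'   `c("s", "u", "v", "b1", "eps")`.
#' @param alpha_bounds,b0_bounds Uniform prior bounds for the intercept and
#'   the global slope.
#' @param beta_sd Gaussian prior standard deviation for regression
#'   coefficients.
#' @param variance_prior `"gamma"` (on precisions; conjugate) or
#'   `"halfnormal"` (on standard deviations).
#' @param prec_shape,prec_rate Gamma prior shape and rate for precisions.
#' @param sd_scale Scale of the half-Gaussian prior on standard deviations.
#' @param v_model Nonlinear yearly deviations `v_t`: `"exchangeable"`
#'   Gaussian (default) or `"rw1"` first-order random walk.
#' @param time_center `"mid"` centers the year index at the mid-period year
#'   (so `alpha` is the mid-period national log-risk); or a number giving
#'   the centering year.
#' @return An `hbstm_spec` list.
#' @export
hbstm_spec <- function(covariates = character(), confounders = character(),
                       effects = c("s", "u", "v", "b1", "eps"),
                       alpha_bounds = c(-50, 50), b0_bounds = c(-50, 50),
                       beta_sd = 10,
                       variance_prior = c("gamma", "halfnormal"),
                       prec_shape = 0.5, prec_rate = 0.0005, sd_scale = 1,
                       v_model = c("exchangeable", "rw1"),
                       time_center = "mid") {
  variance_prior <- match.arg(variance_prior)
  v_model <- match.arg(v_model)
  bad <- setdiff(effects, c("s", "u", "v", "b1", "eps"))
  if (length(bad)) stop("unknown effects: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  stopifnot(beta_sd > 0, prec_shape > 0, prec_rate > 0, sd_scale > 0,
            alpha_bounds[1] < alpha_bounds[2], b0_bounds[1] < b0_bounds[2])
  structure(
    list(
      covariates = covariates, confounders = confounders, effects = effects,
      alpha_bounds = alpha_bounds, b0_bounds = b0_bounds, beta_sd = beta_sd,
      variance_prior = variance_prior, prec_shape = prec_shape,
      prec_rate = prec_rate, sd_scale = sd_scale, v_model = v_model,
      time_center = time_center
    ),
    class = "hbstm_spec"
  )
}

#' Expected death counts by indirect standardization
#'
#' `E_it = sum over strata of population x reference rate`, the denominator
#' of the standardized mortality ratio. With the default internal reference
#' (pooled all-county, all-year stratum-specific rates from the panel
#' itself) the expected counts conserve the observed total:
#' `sum(E) == sum(Y)`.
#'
#' @param panel A `CountyPanel`; stratification uses whichever of `sex` and
#'   `age_group` columns are present.
#' @param reference Optional reference-rate tibble with the stratum columns
#'   and a `rate` column (deaths per person-year); `NULL` pools the panel.
#'   Note the internal reference calibrates the baseline to the panel
#'   (`sum(E) = sum(Y)`), so the fitted intercept measures risk relative to
#'   the panel average, not an external standard; supply the true reference
#'   rates when an absolute baseline is needed (e.g. recovery experiments).
#' @param deaths_col Column holding the death counts to standardize
#'   (default `"deaths_cvd"`; use an adjusted column after preprocessing).
#' @return A tibble `county_id`, `year`, `observed`, `expected`.
#' @export
expected_counts <- function(panel, reference = NULL, deaths_col = "deaths_cvd") {
  panel <- tibble::as_tibble(panel)
  if (any(panel$population <= 0)) stop("populations must be positive", call. = FALSE)
  strata <- intersect(c("sex", "age_group"), names(panel))
  deaths <- panel[[deaths_col]]
  if (is.null(deaths)) stop("no column ", deaths_col, " in panel", call. = FALSE)
  if (is.null(reference)) {
    if (sum(deaths) == 0) {
      stop("internal reference requires a non-zero death total", call. = FALSE)
    }
    if (length(strata)) {
      reference <- dplyr::summarise(
        dplyr::group_by(panel, dplyr::across(dplyr::all_of(strata))),
        rate = sum(.data[[deaths_col]]) / sum(.data$population),
        .groups = "drop"
      )
    } else {
      reference <- tibble::tibble(rate = sum(deaths) / sum(panel$population))
    }
  }
  if (length(strata)) {
    joined <- dplyr::left_join(panel, reference, by = strata)
  } else {
    joined <- panel
    joined$rate <- reference$rate[1]
  }
  if (anyNA(joined$rate)) {
    stop("reference rates missing for some strata", call. = FALSE)
  }
  dplyr::summarise(
    dplyr::group_by(joined, .data$county_id, .data$year),
    observed = sum(.data[[deaths_col]]),
    expected = sum(.data$population * .data$rate),
    .groups = "drop"
  )
}

#' Intrinsic CAR log-density
#'
#' Pairwise-difference log-density of the intrinsic conditional
#' autoregressive prior with precision `tau` on a county graph, up to an
#' additive constant: `-(tau/2) * sum over edges (x_i - x_j)^2` plus the
#' rank-aware normalizing term `((n - c)/2) * log(tau)` with `c` the number
#' of connected components.
#'
#' @param x Numeric vector in graph node order.
#' @param graph A `county_graph`.
#' @param tau Positive precision.
#' @return Log-density value (scalar).
#' @export
icar_logdensity <- function(x, graph, tau) {
  if (length(x) != n_counties(graph)) {
    stop("x must have one value per county", call. = FALSE)
  }
  if (tau <= 0) stop("tau must be positive", call. = FALSE)
  e <- edge_index(graph)
  ss <- sum((x[e[, 1]] - x[e[, 2]])^2)
  n <- length(x)
  cc <- graph_components(graph)$n
  -tau / 2 * ss + (n - cc) / 2 * log(tau)
}

# Log prior of one variance parameter, state stored as precision tau.
variance_logprior <- function(tau, spec) {
  if (spec$variance_prior == "gamma") {
    stats::dgamma(tau, shape = spec$prec_shape, rate = spec$prec_rate, log = TRUE)
  } else {
    # half-Gaussian on sd = tau^(-1/2), with the Jacobian |d sd / d tau|
    sd <- 1 / sqrt(tau)
    log(2) + stats::dnorm(sd, 0, spec$sd_scale, log = TRUE) +
      log(sd / (2 * tau))
  }
}

#' Joint log-posterior of one full parameter state
#'
#' Evaluates the unnormalized log-posterior of the spatiotemporal model:
#' Poisson log-likelihood `sum(Y*eta - E*exp(eta))` (cell constants
#' dropped), intrinsic CAR terms for `s` and `b1`, Gaussian terms for `u`,
#' `v` and `eps`, and the hyperprior terms for each precision. Used by the
#' tests as the single source of truth for the target density; the sampler's
#' incremental acceptance ratios must agree with differences of this
#' function.
#'
#' @param state A named list with elements `alpha`, `b0`, `s`, `u`, `v`,
#'   `b1`, `eps` (county x year matrix), `beta`, and precisions `tau_s`,
#'   `tau_u`, `tau_v`, `tau_b1`, `tau_eps` (only those for included effects
#'   are required).
#' @param Y,E County x year matrices of observed and expected counts.
#' @param graph A `county_graph` (required when `s` or `b1` is included).
#' @param t Centered year index (defaults to a symmetric index around 0).
#' @param X Optional county x covariate matrix.
#' @param spec An [hbstm_spec()].
#' @param parts If `TRUE`, return the named component vector instead of the
#'   sum.
#' @return Scalar log-posterior (or a named vector of components).
#' @export
log_posterior <- function(state, Y, E, graph = NULL, t = NULL, X = NULL,
                          spec = hbstm_spec(), parts = FALSE) {
  Y <- as.matrix(Y)
  E <- as.matrix(E)
  n <- nrow(Y)
  Tn <- ncol(Y)
  if (is.null(t)) t <- seq_len(Tn) - (Tn + 1) / 2
  eff <- spec$effects
  z <- function(k, len) if (is.null(state[[k]])) numeric(len) else state[[k]]
  s <- z("s", n); u <- z("u", n); b1 <- z("b1", n)
  v <- z("v", Tn)
  eps <- if (is.null(state$eps)) matrix(0, n, Tn) else as.matrix(state$eps)
  beta <- state$beta %||% numeric(0)
  xb <- if (length(beta) && !is.null(X)) as.numeric(as.matrix(X) %*% beta) else numeric(n)
  eta <- state$alpha + xb + s + u + eps +
    matrix(state$b0 %||% 0, n, Tn) * matrix(t, n, Tn, byrow = TRUE) +
    matrix(v, n, Tn, byrow = TRUE) + outer(b1, t)
  comp <- c(loglik = sum(Y * eta - E * exp(eta)))
  if (!is.finite(comp["loglik"])) {
    stop("non-finite component: loglik", call. = FALSE)
  }
  inb <- function(x, b) if (x >= b[1] && x <= b[2]) 0 else -Inf
  comp["alpha"] <- inb(state$alpha, spec$alpha_bounds)
  if (!is.null(state$b0)) comp["b0"] <- inb(state$b0, spec$b0_bounds)
  if ("s" %in% eff) {
    comp["s"] <- icar_logdensity(s, graph, state$tau_s)
    comp["tau_s"] <- variance_logprior(state$tau_s, spec)
  }
  if ("u" %in% eff) {
    comp["u"] <- sum(stats::dnorm(u, 0, 1 / sqrt(state$tau_u), log = TRUE))
    comp["tau_u"] <- variance_logprior(state$tau_u, spec)
  }
  if ("v" %in% eff) {
    if (spec$v_model == "rw1") {
      comp["v"] <- -state$tau_v / 2 * sum(diff(v)^2) +
        (Tn - 1) / 2 * log(state$tau_v)
    } else {
      comp["v"] <- sum(stats::dnorm(v, 0, 1 / sqrt(state$tau_v), log = TRUE))
    }
    comp["tau_v"] <- variance_logprior(state$tau_v, spec)
  }
  if ("b1" %in% eff) {
    comp["b1"] <- icar_logdensity(b1, graph, state$tau_b1)
    comp["tau_b1"] <- variance_logprior(state$tau_b1, spec)
  }
  if ("eps" %in% eff) {
    comp["eps"] <- sum(stats::dnorm(eps, 0, 1 / sqrt(state$tau_eps), log = TRUE))
    comp["tau_eps"] <- variance_logprior(state$tau_eps, spec)
  }
  if (length(beta)) {
    comp["beta"] <- sum(stats::dnorm(beta, 0, spec$beta_sd, log = TRUE))
  }
  bad <- names(comp)[!is.finite(comp) & !comp %in% -Inf]
  if (length(bad)) stop("non-finite component: ", bad[1], call. = FALSE)
  if (parts) comp else sum(comp)
}
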