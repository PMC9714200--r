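# Poisson log-density extended continuously to non-integer counts (which
# arise from under-reporting adjustment): y*log(mu) - mu - lgamma(y + 1).
# Coincides with dpois(log = TRUE) at integer y.
poisson_loglik <- function(y, mu) {
  ifelse(mu <= 0, ifelse(y == 0, 0, -Inf),
         y * log(mu) - mu - lgamma(y + 1))
}

#' Fit the spatiotemporal model by adaptive Metropolis-within-Gibbs
#'
#' Samples the posterior of the hierarchical Bayesian spatiotemporal Poisson
#' model with the package's own sampler. Update scheme per sweep:
#' * `alpha`: exact Gibbs — with a flat prior, `exp(alpha)` given everything
#'   else is Gamma(sum(Y), sum(E*exp(eta - alpha))).
#' * `b0`, `beta`: scalar random-walk Metropolis.
#' * `s`, `b1` (intrinsic CAR): single-site random-walk Metropolis,
#'   vectorised over the classes of a proper graph colouring so that no two
#'   counties updated together are neighbours.
#' * `u`, `v`, `eps`: vectorised single-site random-walk Metropolis (their
#'   full conditionals are independent across sites given the rest).
#' * precisions: conjugate gamma Gibbs draws (rank-aware for the CAR terms)
#'   under the gamma prior, log-scale Metropolis under the half-Gaussian
#'   prior.
#'
#' Proposal scales adapt toward a 44% acceptance rate during burn-in and are
#' frozen afterwards. Each sweep re-centers `s`, `v` and `b1` to sum to
#' zero, absorbing their means into `alpha` and `b0`, which leaves the
#' likelihood untouched and pins the intrinsic-CAR identifiability
#' constraint. Split-Rhat and effective sample sizes for all scalar
#' parameters are attached.
#'
#' @param panel A `CountyPanel` (cells are aggregated to county-year).
#' @param graph A `county_graph`; its node order defines all array orders.
#' @param expected Optional tibble `county_id`, `year`, `expected`; computed
#'   by [expected_counts()] from the panel when `NULL`.
#' @param covariates Optional county-level covariate tibble (used when the
#'   spec names covariates); columns are mean-centered internally, and
#'   coefficients are reported per unit of the supplied scale.
#' @param spec An [hbstm_spec()].
#' @param iterations,burn_in,thin,chains MCMC settings; retained draws per
#'   chain are `(iterations - burn_in) / thin`.
#' @param seed Integer seed; chain `k` uses `seed + k - 1`.
#' @param deaths_col Panel column holding the modeled counts.
#' @param verbose Print progress.
#' @return An `hbstm_fit` object: posterior draws of every unknown,
#'   the model data, acceptance rates and convergence diagnostics.
#' @export
fit_hbstm <- function(panel, graph, expected = NULL, covariates = NULL,
                      spec = hbstm_spec(), iterations = 3500, burn_in = 1000,
                      thin = 2, chains = 1, seed = 1,
                      deaths_col = "deaths_cvd", verbose = FALSE) {
  stopifnot(inherits(graph, "county_graph"), iterations > burn_in, burn_in >= 0)
  if (is.null(expected)) {
    expected <- expected_counts(panel, deaths_col = deaths_col)
  }
  ids <- graph$nodes$county_id
  agg <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(panel), .data$county_id, .data$year),
    deaths = sum(.data[[deaths_col]]), .groups = "drop"
  )
  agg <- agg[agg$county_id %in% ids, ]
  if (!nrow(agg)) stop("no modeled cells: panel and graph share no counties",
                       call. = FALSE)
  years <- sort(unique(agg$year))
  n <- length(ids)
  Tn <- length(years)
  Y <- matrix(0, n, Tn, dimnames = list(ids, years))
  Y[cbind(match(agg$county_id, ids), match(agg$year, years))] <- agg$deaths
  E <- matrix(NA_real_, n, Tn)
  ei <- match(expected$county_id, ids)
  keep <- !is.na(ei)
  E[cbind(ei[keep], match(expected$year[keep], years))] <- expected$expected[keep]
  if (anyNA(E)) stop("expected counts missing for some county-years", call. = FALSE)
  if (any(E <= 0)) stop("expected counts must be positive", call. = FALSE)
  tvec <- if (identical(spec$time_center, "mid")) {
    years - (min(years) + max(years)) / 2
  } else {
    years - as.numeric(spec$time_center)
  }
  xcols <- c(spec$covariates, spec$confounders)
  X <- NULL
  x_center <- NULL
  if (length(xcols)) {
    if (is.null(covariates)) stop("spec names covariates but none supplied",
                                  call. = FALSE)
    miss <- setdiff(xcols, names(covariates))
    if (length(miss)) stop("covariate columns missing: ",
                           paste(miss, collapse = ", "), call. = FALSE)
    X <- as.matrix(covariates[match(ids, covariates$county_id), xcols,
                              drop = FALSE])
    if (anyNA(X)) stop("covariates missing for some counties (impute first)",
                       call. = FALSE)
    x_center <- colMeans(X)
    X <- sweep(X, 2, x_center)
  }
  fixed <- list(Y = Y, E = E, tvec = tvec, X = X, graph = graph, spec = spec,
                n = n, Tn = Tn)
  chain_out <- vector("list", chains)
  for (ch in seq_len(chains)) {
    chain_out[[ch]] <- run_chain(fixed, iterations, burn_in, thin,
                                 seed = seed + ch - 1, verbose = verbose)
  }
  draws <- combine_chains(chain_out)
  fit <- structure(
    list(
      draws = draws$draws, chain = draws$chain,
      data = list(Y = Y, E = E, tvec = tvec, years = years,
                  county_id = ids, X = X, x_center = x_center),
      spec = spec, graph = graph,
      mcmc = list(iterations = iterations, burn_in = burn_in, thin = thin,
                  chains = chains, seed = seed),
      acceptance = chain_out[[1]]$acceptance
    ),
    class = "hbstm_fit"
  )
  fit$diagnostics <- fit_diagnostics(fit)
  fit
}

# One MCMC chain. fixed holds the immutable data; returns stored draws.
run_chain <- function(fixed, iterations, burn_in, thin, seed, verbose = FALSE) {
  set.seed(seed)
  Y <- fixed$Y; E <- fixed$E; tvec <- fixed$tvec; X <- fixed$X
  spec <- fixed$spec; n <- fixed$n; Tn <- fixed$Tn
  eff <- spec$effects
  has <- function(k) k %in% eff
  fit_b0 <- Tn > 1
  p <- if (is.null(X)) 0L else ncol(X)
  W <- if (has("s") || has("b1")) adjacency_matrix(fixed$graph) else NULL
  deg <- if (!is.null(W)) Matrix::rowSums(W) else NULL
  colors <- if (has("s") || has("b1")) graph_coloring(fixed$graph) else NULL
  ncomp <- if (!is.null(W)) graph_components(fixed$graph)$n else 1L
  edges <- if (!is.null(W)) edge_index(fixed$graph) else NULL
  rowY <- rowSums(Y); colY <- colSums(Y); sumY <- sum(Y)
  rowYt <- as.numeric(Y %*% tvec); sumYt <- sum(colY * tvec)
  gamma_prior <- spec$variance_prior == "gamma"
  a0 <- spec$prec_shape; r0 <- spec$prec_rate

  # state
  alpha <- log(max(sumY, 0.5) / sum(E))
  b0 <- 0
  s <- numeric(n); u <- numeric(n); v <- numeric(Tn); b1 <- numeric(n)
  eps <- matrix(0, n, Tn)
  beta <- numeric(p)
  tau <- c(s = 100, u = 100, v = 400, b1 = 10000, eps = 400)
  eta <- matrix(alpha, n, Tn) + matrix(b0 * tvec, n, Tn, byrow = TRUE)

  step <- c(b0 = 0.01, beta = 0.05, s = 0.1, u = 0.1, v = 0.05,
            b1 = 0.01, eps = 0.1, tau = 0.5,
            shift_a = 0.05, shift_b0 = 0.01, shift_beta = 0.05,
            shift_u = 0.05, swap_su = 0.1, swap_ue = 0.1, shift_b0v = 0.005,
            scale_s = 0.1, scale_u = 0.2, swap_bs = 0.05, swap_bu = 0.05)
  acc_sum <- step * 0; acc_n <- step * 0

  n_store <- (iterations - burn_in) %/% thin
  S <- list(
    alpha = numeric(n_store), b0 = numeric(n_store),
    beta = matrix(0, n_store, p),
    s = matrix(0, n_store, n), u = matrix(0, n_store, n),
    v = matrix(0, n_store, Tn), b1 = matrix(0, n_store, n),
    eps = matrix(0, n_store, n * Tn),
    sd = matrix(0, n_store, 5, dimnames = list(NULL, names(tau))),
    loglik = numeric(n_store)
  )
  if (p) colnames(S$beta) <- colnames(X)
  store_i <- 0L

  tune <- function(fam, acc, iter) {
    if (iter <= burn_in) {
      g <- min(0.25, iter^-0.6)
      step[fam] <<- exp(log(step[fam]) + g * (acc - 0.44))
    }
    acc_sum[fam] <<- acc_sum[fam] + acc
    acc_n[fam] <<- acc_n[fam] + 1
  }

  car_dprior <- function(x, dx, idx, tau_x, nbsum) {
    # change in -(tau/2) * sum_j w_ij (x_i - x_j)^2 when x[idx] += dx
    xi <- x[idx]
    -tau_x / 2 * (deg[idx] * ((xi + dx)^2 - xi^2) - 2 * dx * nbsum[idx])
  }

  for (iter in seq_len(iterations)) {
    M <- E * exp(eta)

    # alpha: exact Gibbs on exp(alpha) under the flat prior
    Cg <- sum(M) * exp(-alpha)
    a_new <- log(stats::rgamma(1, shape = sumY + 1e-12, rate = Cg))
    if (a_new >= spec$alpha_bounds[1] && a_new <= spec$alpha_bounds[2]) {
      eta <- eta + (a_new - alpha)
      M <- M * exp(a_new - alpha)
      alpha <- a_new
    }

    if (fit_b0) {
      d <- stats::rnorm(1, 0, step["b0"])
      colM <- colSums(M)
      lr <- d * sumYt - sum(colM * (exp(d * tvec) - 1))
      ok <- (b0 + d) >= spec$b0_bounds[1] && (b0 + d) <= spec$b0_bounds[2]
      if (ok && log(stats::runif(1)) < lr) {
        b0 <- b0 + d
        eta <- eta + matrix(d * tvec, n, Tn, byrow = TRUE)
        M <- E * exp(eta)
        tune("b0", 1, iter)
      } else tune("b0", 0, iter)
    }

    if (p) {
      for (k in seq_len(p)) {
        xk <- X[, k]
        d <- stats::rnorm(1, 0, step["beta"])
        rowM <- rowSums(M)
        lr <- d * sum(rowY * xk) - sum(rowM * (exp(d * xk) - 1)) +
          stats::dnorm(beta[k] + d, 0, spec$beta_sd, log = TRUE) -
          stats::dnorm(beta[k], 0, spec$beta_sd, log = TRUE)
        if (log(stats::runif(1)) < lr) {
          beta[k] <- beta[k] + d
          eta <- eta + d * xk
          M <- M * exp(d * xk)
          tune("beta", 1, iter)
        } else tune("beta", 0, iter)
      }
    }

    if (has("s")) {
      acc_tot <- 0
      for (cl in colors) {
        rowM <- rowSums(M)
        nbsum <- as.numeric(W %*% s)
        d <- stats::rnorm(length(cl), 0, step["s"])
        lr <- d * rowY[cl] - rowM[cl] * (exp(d) - 1) +
          car_dprior(s, d, cl, tau["s"], nbsum)
        acc <- log(stats::runif(length(cl))) < lr
        if (any(acc)) {
          ci <- cl[acc]
          s[ci] <- s[ci] + d[acc]
          eta[ci, ] <- eta[ci, ] + d[acc]
          M[ci, ] <- M[ci, ] * exp(d[acc])
        }
        acc_tot <- acc_tot + sum(acc)
      }
      tune("s", acc_tot / n, iter)
    }

    if (has("u")) {
      rowM <- rowSums(M)
      d <- stats::rnorm(n, 0, step["u"])
      lr <- d * rowY - rowM * (exp(d) - 1) -
        tau["u"] / 2 * ((u + d)^2 - u^2)
      acc <- log(stats::runif(n)) < lr
      if (any(acc)) {
        u[acc] <- u[acc] + d[acc]
        eta[acc, ] <- eta[acc, ] + d[acc]
        M[acc, ] <- M[acc, ] * exp(d[acc])
      }
      tune("u", mean(acc), iter)
    }

    if (has("v") && Tn > 1) {
      colM <- colSums(M)
      d <- stats::rnorm(Tn, 0, step["v"])
      if (spec$v_model == "rw1") {
        acc_tot <- 0
        for (par in list(seq(1, Tn, 2), seq(2, Tn, 2))) {
          dd <- d[par]
          prev <- ifelse(par > 1, v[pmax(par - 1, 1)], NA)
          nxt <- ifelse(par < Tn, v[pmin(par + 1, Tn)], NA)
          nb <- rowSums(cbind(prev, nxt), na.rm = TRUE)
          k <- (par > 1) + (par < Tn)
          vp <- v[par]
          dpr <- -tau["v"] / 2 * (k * ((vp + dd)^2 - vp^2) - 2 * dd * nb)
          lr <- dd * colY[par] - colM[par] * (exp(dd) - 1) + dpr
          acc <- log(stats::runif(length(par))) < lr
          ti <- par[acc]
          if (length(ti)) {
            v[ti] <- v[ti] + dd[acc]
            eta[, ti] <- sweep(eta[, ti, drop = FALSE], 2, dd[acc], `+`)
            M[, ti] <- sweep(M[, ti, drop = FALSE], 2, exp(dd[acc]), `*`)
            colM <- colSums(M)
          }
          acc_tot <- acc_tot + sum(acc)
        }
        tune("v", acc_tot / Tn, iter)
      } else {
        lr <- d * colY - colM * (exp(d) - 1) -
          tau["v"] / 2 * ((v + d)^2 - v^2)
        acc <- log(stats::runif(Tn)) < lr
        ti <- which(acc)
        if (length(ti)) {
          v[ti] <- v[ti] + d[ti]
          eta[, ti] <- sweep(eta[, ti, drop = FALSE], 2, d[ti], `+`)
          M[, ti] <- sweep(M[, ti, drop = FALSE], 2, exp(d[ti]), `*`)
        }
        tune("v", mean(acc), iter)
      }
    }

    if (has("b1") && Tn > 1) {
      acc_tot <- 0
      for (cl in colors) {
        nbsum <- as.numeric(W %*% b1)
        d <- stats::rnorm(length(cl), 0, step["b1"])
        grow <- exp(outer(d, tvec)) - 1
        lr <- d * rowYt[cl] - rowSums(M[cl, , drop = FALSE] * grow) +
          car_dprior(b1, d, cl, tau["b1"], nbsum)
        acc <- log(stats::runif(length(cl))) < lr
        if (any(acc)) {
          ci <- cl[acc]
          mult <- exp(outer(d[acc], tvec))
          eta[ci, ] <- eta[ci, ] + outer(d[acc], tvec)
          M[ci, ] <- M[ci, ] * mult
          b1[ci] <- b1[ci] + d[acc]
        }
        acc_tot <- acc_tot + sum(acc)
      }
      tune("b1", acc_tot / n, iter)
    }

    if (has("eps")) {
      d <- matrix(stats::rnorm(n * Tn, 0, step["eps"]), n, Tn)
      lr <- d * Y - M * (exp(d) - 1) -
        tau["eps"] / 2 * ((eps + d)^2 - eps^2)
      acc <- matrix(log(stats::runif(n * Tn)), n, Tn) < lr
      eps[acc] <- eps[acc] + d[acc]
      eta[acc] <- eta[acc] + d[acc]
      tune("eps", mean(acc), iter)
    }

    # likelihood-invariant shift moves: trade the global parameters against
    # the free means of the exchangeable effects (alpha vs u, alpha vs eps,
    # b0 and beta vs the matching component of eps). eta is unchanged, so
    # only the Gaussian priors enter the acceptance ratio; these moves
    # decorrelate the slowly mixing sums.
    in_a <- function(x) x >= spec$alpha_bounds[1] && x <= spec$alpha_bounds[2]
    if (has("u")) {
      d <- stats::rnorm(1, 0, step["shift_u"])
      lr <- -tau["u"] / 2 * (n * d^2 - 2 * d * sum(u))
      if (in_a(alpha + d) && log(stats::runif(1)) < lr) {
        alpha <- alpha + d
        u <- u - d
        tune("shift_u", 1, iter)
      } else tune("shift_u", 0, iter)
    }
    if (has("eps")) {
      d <- stats::rnorm(1, 0, step["shift_a"])
      lr <- -tau["eps"] / 2 * (n * Tn * d^2 - 2 * d * sum(eps))
      if (in_a(alpha + d) && log(stats::runif(1)) < lr) {
        alpha <- alpha + d
        eps <- eps - d
        tune("shift_a", 1, iter)
      } else tune("shift_a", 0, iter)
      if (fit_b0) {
        d <- stats::rnorm(1, 0, step["shift_b0"])
        c1 <- sum(as.numeric(eps %*% tvec))
        c2 <- n * sum(tvec^2)
        lr <- -tau["eps"] / 2 * (d^2 * c2 - 2 * d * c1)
        ok <- (b0 + d) >= spec$b0_bounds[1] && (b0 + d) <= spec$b0_bounds[2]
        if (ok && log(stats::runif(1)) < lr) {
          b0 <- b0 + d
          eps <- eps - matrix(d * tvec, n, Tn, byrow = TRUE)
          tune("shift_b0", 1, iter)
        } else tune("shift_b0", 0, iter)
      }
      if (p) {
        for (k in seq_len(p)) {
          xk <- X[, k]
          d <- stats::rnorm(1, 0, step["shift_beta"])
          lr <- -tau["eps"] / 2 * (d^2 * Tn * sum(xk^2) -
                                     2 * d * sum(xk * rowSums(eps))) +
            stats::dnorm(beta[k] + d, 0, spec$beta_sd, log = TRUE) -
            stats::dnorm(beta[k], 0, spec$beta_sd, log = TRUE)
          if (log(stats::runif(1)) < lr) {
            beta[k] <- beta[k] + d
            eps <- eps - d * xk
            tune("shift_beta", 1, iter)
          } else tune("shift_beta", 0, iter)
        }
      }
    }

    M <- E * exp(eta)

    # amplitude rescaling: multiply a whole effect vector by exp(z), the
    # slow direction of the structured/unstructured variance split. The
    # Jacobian is r^rank on the effect's support (the centered subspace for
    # the intrinsic CAR).
    scale_move <- function(fam, x, rank_eff, prior_ss_fn) {
      r <- exp(stats::rnorm(1, 0, step[paste0("scale_", fam)]))
      dx <- (r - 1) * x
      rowM <- rowSums(M)
      lr <- sum(dx * rowY - rowM * (exp(dx) - 1)) -
        tau[fam] / 2 * (r^2 - 1) * prior_ss_fn(x) + rank_eff * log(r)
      if (log(stats::runif(1)) < lr) {
        eta <<- eta + dx
        M <<- M * exp(dx)
        tune(paste0("scale_", fam), 1, iter)
        x * r
      } else {
        tune(paste0("scale_", fam), 0, iter)
        x
      }
    }
    # prior-only swap moves within the linear predictor redistribute the
    # same fitted surface between weakly identified component pairs
    # (structured vs unstructured spatial effect; unstructured effect vs
    # noise row means; global slope vs the linear-in-t component of v).
    # The s/u block cycles a few times with fresh precision draws because
    # the variance split is the sampler's slowest direction.
    for (mix_rep in 1:3) {
      if (has("s")) {
        ss_fn <- function(x) sum((x[edges[, 1]] - x[edges[, 2]])^2)
        s <- scale_move("s", s, n - ncomp, ss_fn)
        if (gamma_prior) {
          tau["s"] <- stats::rgamma(1, shape = a0 + (n - ncomp) / 2,
                                    rate = r0 + ss_fn(s) / 2)
        }
      }
      if (has("u")) {
        u <- scale_move("u", u, n, function(x) sum(x^2))
        if (gamma_prior) {
          tau["u"] <- stats::rgamma(1, shape = a0 + n / 2,
                                    rate = r0 + sum(u^2) / 2)
        }
      }
      if (has("s") && has("u")) {
        acc_tot <- 0
        for (cl in colors) {
          nbsum <- as.numeric(W %*% s)
          d <- stats::rnorm(length(cl), 0, step["swap_su"])
          lr <- car_dprior(s, d, cl, tau["s"], nbsum) -
            tau["u"] / 2 * ((u[cl] - d)^2 - u[cl]^2)
          acc <- log(stats::runif(length(cl))) < lr
          ci <- cl[acc]
          s[ci] <- s[ci] + d[acc]
          u[ci] <- u[ci] - d[acc]
          acc_tot <- acc_tot + sum(acc)
        }
        tune("swap_su", acc_tot / n, iter)
      }
    }
    if (has("u") && has("eps")) {
      d <- stats::rnorm(n, 0, step["swap_ue"])
      lr <- -tau["u"] / 2 * ((u + d)^2 - u^2) -
        tau["eps"] / 2 * (Tn * d^2 - 2 * d * rowSums(eps))
      acc <- log(stats::runif(n)) < lr
      u[acc] <- u[acc] + d[acc]
      eps[acc, ] <- eps[acc, , drop = FALSE] - d[acc]
      tune("swap_ue", mean(acc), iter)
    }
    # spatial-confounding ridge: trade each coefficient against the
    # projection of the spatial fields onto its (centered) covariate,
    # leaving the linear predictor unchanged
    if (p && has("s")) {
      for (k in seq_len(p)) {
        xk <- X[, k]
        dxk <- xk[edges[, 1]] - xk[edges[, 2]]
        d <- stats::rnorm(1, 0, step["swap_bs"])
        sdiff <- s[edges[, 1]] - s[edges[, 2]]
        lr <- -tau["s"] / 2 * (d^2 * sum(dxk^2) - 2 * d * sum(sdiff * dxk)) +
          stats::dnorm(beta[k] + d, 0, spec$beta_sd, log = TRUE) -
          stats::dnorm(beta[k], 0, spec$beta_sd, log = TRUE)
        if (log(stats::runif(1)) < lr) {
          beta[k] <- beta[k] + d
          s <- s - d * xk
          tune("swap_bs", 1, iter)
        } else tune("swap_bs", 0, iter)
      }
    }
    if (p && has("u")) {
      for (k in seq_len(p)) {
        xk <- X[, k]
        d <- stats::rnorm(1, 0, step["swap_bu"])
        lr <- -tau["u"] / 2 * (d^2 * sum(xk^2) - 2 * d * sum(u * xk)) +
          stats::dnorm(beta[k] + d, 0, spec$beta_sd, log = TRUE) -
          stats::dnorm(beta[k], 0, spec$beta_sd, log = TRUE)
        if (log(stats::runif(1)) < lr) {
          beta[k] <- beta[k] + d
          u <- u - d * xk
          tune("swap_bu", 1, iter)
        } else tune("swap_bu", 0, iter)
      }
    }
    if (has("v") && fit_b0) {
      d <- stats::rnorm(1, 0, step["shift_b0v"])
      if (spec$v_model == "rw1") {
        lr <- -tau["v"] / 2 * (sum(diff(v - d * tvec)^2) - sum(diff(v)^2))
      } else {
        lr <- -tau["v"] / 2 * (d^2 * sum(tvec^2) - 2 * d * sum(v * tvec))
      }
      ok <- (b0 + d) >= spec$b0_bounds[1] && (b0 + d) <= spec$b0_bounds[2]
      if (ok && log(stats::runif(1)) < lr) {
        b0 <- b0 + d
        v <- v - d * tvec
        tune("shift_b0v", 1, iter)
      } else tune("shift_b0v", 0, iter)
    }

    # re-center: means of s, v, b1 are absorbed into alpha and b0, leaving
    # the linear predictor (hence eta) unchanged
    if (has("s")) { m <- mean(s); s <- s - m; alpha <- alpha + m }
    if (has("v") && Tn > 1) { m <- mean(v); v <- v - m; alpha <- alpha + m }
    if (has("b1") && Tn > 1) { m <- mean(b1); b1 <- b1 - m; b0 <- b0 + m }

    # variance parameters
    upd_tau <- function(fam, rank_eff, ss) {
      if (gamma_prior) {
        stats::rgamma(1, shape = a0 + rank_eff / 2, rate = r0 + ss / 2)
      } else {
        # Metropolis on log(tau) under the half-Gaussian sd prior
        cur <- tau[fam]
        prop <- cur * exp(stats::rnorm(1, 0, step["tau"]))
        lp <- function(tt) {
          rank_eff / 2 * log(tt) - tt / 2 * ss + variance_logprior(tt, spec)
        }
        lr <- lp(prop) - lp(cur) + log(prop) - log(cur)
        if (log(stats::runif(1)) < lr) prop else cur
      }
    }
    if (has("s")) {
      ss <- sum((s[edges[, 1]] - s[edges[, 2]])^2)
      tau["s"] <- upd_tau("s", n - ncomp, ss)
    }
    if (has("u")) tau["u"] <- upd_tau("u", n, sum(u^2))
    if (has("v") && Tn > 1) {
      if (spec$v_model == "rw1") {
        tau["v"] <- upd_tau("v", Tn - 1, sum(diff(v)^2))
      } else {
        tau["v"] <- upd_tau("v", Tn, sum(v^2))
      }
    }
    if (has("b1") && Tn > 1) {
      ss <- sum((b1[edges[, 1]] - b1[edges[, 2]])^2)
      tau["b1"] <- upd_tau("b1", n - ncomp, ss)
    }
    if (has("eps")) tau["eps"] <- upd_tau("eps", n * Tn, sum(eps^2))

    if (iter > burn_in && (iter - burn_in) %% thin == 0) {
      store_i <- store_i + 1L
      S$alpha[store_i] <- alpha
      S$b0[store_i] <- b0
      if (p) S$beta[store_i, ] <- beta
      S$s[store_i, ] <- s
      S$u[store_i, ] <- u
      S$v[store_i, ] <- v
      S$b1[store_i, ] <- b1
      S$eps[store_i, ] <- as.numeric(eps)
      S$sd[store_i, ] <- 1 / sqrt(tau)
      S$loglik[store_i] <- sum(poisson_loglik(Y, E * exp(eta)))
    }
    if (verbose && iter %% 500 == 0) {
      message("iteration ", iter, " / ", iterations)
    }
  }
  list(draws = S, acceptance = ifelse(acc_n > 0, acc_sum / acc_n, NA))
}

combine_chains <- function(chain_out) {
  ds <- lapply(chain_out, `[[`, "draws")
  nm <- names(ds[[1]])
  draws <- stats::setNames(lapply(nm, function(k) {
    if (is.matrix(ds[[1]][[k]])) {
      do.call(rbind, lapply(ds, `[[`, k))
    } else {
      do.call(c, lapply(ds, `[[`, k))
    }
  }), nm)
  chain <- rep(seq_along(ds), each = length(ds[[1]]$alpha))
  list(draws = draws, chain = chain)
}

# --- convergence diagnostics -------------------------------------------------

# Split-Rhat: each chain is halved, then the usual between/within variance
# ratio is computed over the resulting sub-chains.
split_rhat <- function(x, chain) {
  parts <- unlist(lapply(split(x, chain), function(z) {
    h <- length(z) %/% 2
    if (h < 2) return(list(z))
    list(z[1:h], z[(h + 1):(2 * h)])
  }), recursive = FALSE)
  l <- min(lengths(parts))
  parts <- lapply(parts, function(z) z[seq_len(l)])
  m <- length(parts)
  if (m < 2 || l < 2) return(NA_real_)
  means <- vapply(parts, mean, numeric(1))
  vars <- vapply(parts, stats::var, numeric(1))
  Wv <- mean(vars)
  Bv <- l * stats::var(means)
  if (Wv < .Machine$double.eps) return(1)
  sqrt(((l - 1) / l * Wv + Bv / l) / Wv)
}

# Effective sample size via Geyer's initial positive sequence, averaged over
# chains.
ess_basic <- function(x, chain) {
  per <- split(x, chain)
  l <- min(lengths(per))
  if (l < 4) return(NA_real_)
  rho_sum <- 0
  for (z in per) {
    z <- z[seq_len(l)]
    if (stats::var(z) < .Machine$double.eps) next
    ac <- stats::acf(z, lag.max = min(l - 2, 200), plot = FALSE)$acf[-1]
    pair <- ac[seq(1, length(ac) - 1, by = 2)] + ac[seq(2, length(ac), by = 2)]
    kmax <- which(pair <= 0)[1]
    if (is.na(kmax)) kmax <- length(pair) + 1
    keep <- if (kmax > 1) ac[seq_len(2 * (kmax - 1))] else numeric(0)
    rho_sum <- rho_sum + sum(keep)
  }
  rho <- rho_sum / length(per)
  ess <- length(per) * l / (1 + 2 * max(rho, 0))
  min(ess, length(x))
}

fit_diagnostics <- function(fit) {
  d <- fit$draws
  scal <- list(alpha = d$alpha)
  if (length(fit$data$tvec) > 1) scal$b0 <- d$b0
  if (ncol(d$beta) > 0) {
    for (k in colnames(d$beta)) scal[[paste0("beta_", k)]] <- d$beta[, k]
  }
  for (k in colnames(d$sd)) {
    if (stats::sd(d$sd[, k]) > 0) scal[[paste0("sd_", k)]] <- log(d$sd[, k])
  }
  tibble::tibble(
    parameter = names(scal),
    rhat = vapply(scal, split_rhat, numeric(1), chain = fit$chain),
    ess = vapply(scal, ess_basic, numeric(1), chain = fit$chain)
  )
}

#' Posterior draws of the relative risk surface
#'
#' Reconstructs `theta_it = exp(eta_it)` per retained draw from the stored
#' components.
#'
#' @param fit An `hbstm_fit`.
#' @param years Years to include (default all).
#' @return A draws x county x year array of relative risks.
#' @export
theta_draws <- function(fit, years = NULL) {
  d <- fit$draws
  yrs <- fit$data$years
  sel <- if (is.null(years)) seq_along(yrs) else match(years, yrs)
  if (anyNA(sel)) stop("year not in fit: ",
                       paste(years[is.na(sel)], collapse = ", "), call. = FALSE)
  n <- length(fit$data$county_id)
  D <- length(d$alpha)
  xb <- if (!is.null(fit$data$X) && ncol(d$beta) > 0) {
    d$beta %*% t(fit$data$X[, colnames(d$beta), drop = FALSE])
  } else {
    matrix(0, D, n)
  }
  out <- array(NA_real_, c(D, n, length(sel)),
               dimnames = list(NULL, fit$data$county_id, yrs[sel]))
  for (j in seq_along(sel)) {
    tt <- fit$data$tvec[sel[j]]
    epsj <- d$eps[, (sel[j] - 1) * n + seq_len(n), drop = FALSE]
    out[, , j] <- exp(d$alpha + xb + d$s + d$u + d$b0 * tt + d$v[, sel[j]] +
                        d$b1 * tt + epsj)
  }
  out
}

#' Deviance-based model comparison scores
#'
#' Computes the posterior-mean deviance, DIC and WAIC from the per-cell
#' Poisson log-likelihood of each retained draw. The effective number of
#' parameters is `p_DIC = mean(D) - D(posterior mean eta)` and
#' `p_WAIC = sum over cells of the posterior variance of the log-likelihood`.
#'
#' @param fit An `hbstm_fit` with at least 50 retained draws.
#' @return A one-row tibble with `dbar`, `dic`, `p_dic`, `waic`, `p_waic`
#'   and `lppd`.
#' @export
information_criterion <- function(fit) {
  d <- fit$draws
  D <- length(d$alpha)
  if (D < 50) stop("need at least 50 retained draws", call. = FALSE)
  Y <- fit$data$Y; E <- fit$data$E
  n <- nrow(Y); Tn <- ncol(Y)
  yv <- as.numeric(Y); ev <- as.numeric(E)
  LL <- matrix(NA_real_, D, n * Tn)
  eta_bar <- numeric(n * Tn)
  th <- theta_draws(fit)
  for (dd in seq_len(D)) {
    eta <- log(as.numeric(th[dd, , ]))
    LL[dd, ] <- poisson_loglik(yv, ev * exp(eta))
    eta_bar <- eta_bar + eta / D
  }
  dev <- -2 * rowSums(LL)
  dbar <- mean(dev)
  dhat <- -2 * sum(poisson_loglik(yv, ev * exp(eta_bar)))
  p_dic <- dbar - dhat
  # log pointwise predictive density with a stable log-mean-exp
  mx <- apply(LL, 2, max)
  lppd <- sum(mx + log(colMeans(exp(sweep(LL, 2, mx)))))
  p_waic <- sum(apply(LL, 2, stats::var))
  tibble::tibble(
    dbar = dbar, dic = dbar + p_dic, p_dic = p_dic,
    waic = -2 * (lppd - p_waic), p_waic = p_waic, lppd = lppd
  )
}
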