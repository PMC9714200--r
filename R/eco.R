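#' Multiple imputation of county covariates
#'
#' Fills missing covariate values by chained regressions with
#' predictive-mean matching: each incomplete column is regressed on the
#' others, and every missing cell receives the observed value of one of the
#' `k` donors whose fitted values are nearest its own prediction. The chain
#' sweeps all incomplete columns several times; `m` independent chains give
#' `m` completed tables whose downstream posteriors are pooled.
#'
#' @param table Covariate tibble with a `county_id` column; only numeric
#'   columns are imputed.
#' @param m Number of completed tables (default 5).
#' @param seed Integer seed.
#' @param sweeps Chained-regression sweeps per table (default 5).
#' @param k Donor pool size for predictive-mean matching (default 5).
#' @return A list of `m` completed tibbles. With no missing values all
#'   tables equal the input.
#' @export
impute_covariates <- function(table, m = 5, seed = 1, sweeps = 5, k = 5) {
  if (!is.numeric(m) || length(m) != 1 || m < 1) {
    stop("m must be a positive integer", call. = FALSE)
  }
  table <- tibble::as_tibble(table)
  num_cols <- names(table)[vapply(table, is.numeric, logical(1))]
  num_cols <- setdiff(num_cols, "county_id")
  frac_obs <- vapply(table[num_cols], function(x) mean(!is.na(x)), numeric(1))
  if (any(frac_obs < 0.5)) {
    stop("covariate(s) less than 50% observed: ",
         paste(num_cols[frac_obs < 0.5], collapse = ", "), call. = FALSE)
  }
  incomplete <- num_cols[frac_obs < 1]
  if (!length(incomplete)) return(replicate(m, table, simplify = FALSE))
  set.seed(seed)
  lapply(seq_len(m), function(imp) {
    filled <- table
    for (cn in incomplete) {
      x <- filled[[cn]]
      x[is.na(x)] <- mean(x, na.rm = TRUE)
      filled[[cn]] <- x
    }
    for (sw in seq_len(sweeps)) {
      for (cn in incomplete) {
        miss <- is.na(table[[cn]])
        preds <- setdiff(num_cols, cn)
        Xm <- as.matrix(filled[preds])
        keepcol <- apply(Xm, 2, function(z) stats::sd(z) > 0)
        Xm <- cbind(1, Xm[, keepcol, drop = FALSE])
        fitc <- stats::lm.fit(Xm[!miss, , drop = FALSE], table[[cn]][!miss])
        yhat_obs <- Xm[!miss, , drop = FALSE] %*% fitc$coefficients
        yhat_mis <- Xm[miss, , drop = FALSE] %*% fitc$coefficients
        obs_vals <- table[[cn]][!miss]
        donor <- vapply(yhat_mis, function(yh) {
          nn <- order(abs(yhat_obs - yh))[seq_len(min(k, length(obs_vals)))]
          obs_vals[sample(nn, 1)]
        }, numeric(1))
        x <- filled[[cn]]
        x[miss] <- donor
        filled[[cn]] <- x
      }
    }
    filled
  })
}

#' Put covariates on their model units
#'
#' Scales each focal covariate so the regression coefficient is per the
#' reporting unit (GDP per 10,000 yuan per person, NTL/NB/PD per one unit —
#' the identity when the table is already in those units), and z-scores the
#' confounders. The applied centers and scales are attached as the
#' `"scaling"` attribute so the transformation is invertible.
#'
#' @param table Complete covariate tibble.
#' @param focal Focal covariate columns (left on their stated units).
#' @param confounders Confounder columns (z-scored).
#' @param focal_divisors Optional named divisors for focal columns (e.g.
#'   `c(GDP = 10)` if GDP arrives in thousands of yuan rather than
#'   10,000-yuan units).
#' @return The rescaled tibble with a `"scaling"` attribute.
#' @export
standardize_covariates <- function(table,
                                   focal = c("GDP", "NTL", "NB", "PD"),
                                   confounders = c("TEMP", "TV", "HUMID",
                                                   "LT", "AT", "PM25"),
                                   focal_divisors = NULL) {
  table <- tibble::as_tibble(table)
  focal <- intersect(focal, names(table))
  confounders <- intersect(confounders, names(table))
  if (anyNA(table[c(focal, confounders)])) {
    stop("covariates contain missing values; impute first", call. = FALSE)
  }
  scaling <- list()
  for (cn in c(focal, confounders)) {
    if (stats::sd(table[[cn]]) == 0) {
      stop("zero-variance covariate: ", cn, call. = FALSE)
    }
  }
  for (cn in focal) {
    div <- if (!is.null(focal_divisors) && cn %in% names(focal_divisors)) {
      focal_divisors[[cn]]
    } else 1
    table[[cn]] <- table[[cn]] / div
    scaling[[cn]] <- list(center = 0, scale = div)
  }
  for (cn in confounders) {
    mu <- mean(table[[cn]])
    sdv <- stats::sd(table[[cn]])
    table[[cn]] <- (table[[cn]] - mu) / sdv
    scaling[[cn]] <- list(center = mu, scale = sdv)
  }
  attr(table, "scaling") <- scaling
  table
}

#' Relative-risk summary of a coefficient's posterior
#'
#' Exponentiates the coefficient draws to relative risks and reports the
#' posterior median, the 2.5th-97.5th percentile credible interval, the
#' posterior probability of a protective association (`P(RR < 1 | data)`,
#' the fraction of draws below 0 on the log scale; exactly-null draws split
#' evenly so an all-zero posterior reports 0.5), and the implied percent
#' change in risk per covariate unit (`(1 - RR) * 100`; negative values
#' mean an increase).
#'
#' @param beta_draws Posterior draws of the coefficient (log-RR scale).
#' @param covariate Covariate name for the output row.
#' @param min_draws Error below this many draws (default 100).
#' @return A one-row `EcoEffect` tibble: `covariate`, `rr`, `rr_lo`,
#'   `rr_hi`, `prob_protective`, `pct_decrease`.
#' @export
rr_summary <- function(beta_draws, covariate = "x", min_draws = 100) {
  if (!length(beta_draws)) stop("empty draws", call. = FALSE)
  if (length(beta_draws) < min_draws) {
    warning("fewer than ", min_draws, " draws; summaries are noisy",
            call. = FALSE)
  }
  rr <- exp(beta_draws)
  q <- stats::quantile(rr, c(0.025, 0.5, 0.975), names = FALSE)
  prob <- mean(beta_draws < 0) + 0.5 * mean(beta_draws == 0)
  tibble::tibble(
    covariate = covariate,
    rr = q[2], rr_lo = q[1], rr_hi = q[3],
    prob_protective = prob,
    pct_decrease = (1 - q[2]) * 100
  )
}

#' Ecological regression nationally and by region
#'
#' Fits the covariate-extended spatiotemporal model once on the full data
#' and once per region subset (with the CAR prior restricted to the
#' region's induced subgraph), then tabulates every focal covariate as a
#' relative risk with credible interval and posterior protective
#' probability — one row per region x covariate. With multiply imputed
#' covariate tables, fits run per completion and the coefficient draws are
#' pooled before summarizing.
#'
#' @param panel A `CountyPanel`.
#' @param graph A `county_graph` whose nodes carry a `region` column (or
#'   pass `regions`).
#' @param covariates A completed covariate table, or a list of them from
#'   [impute_covariates()].
#' @param spec An [hbstm_spec()] naming the covariates and confounders.
#' @param regions Optional tibble `county_id`, `region` overriding the
#'   graph's labels.
#' @param min_counties Regions below this size are skipped with a warning.
#' @param ... Passed to [fit_hbstm()] (`iterations`, `burn_in`, `seed`, ...).
#' @return A tibble of `EcoEffect` rows with a `region` column ("nationwide"
#'   first), and the list of fitted national models as the `"fits"`
#'   attribute.
#' @export
fit_regional <- function(panel, graph, covariates, spec, regions = NULL,
                         min_counties = 10, ...) {
  if (!is.list(covariates) || is.data.frame(covariates)) {
    covariates <- list(covariates)
  }
  region_of <- if (!is.null(regions)) {
    stats::setNames(regions$region, regions$county_id)
  } else if (!is.null(graph$nodes$region)) {
    stats::setNames(graph$nodes$region, graph$nodes$county_id)
  } else {
    stop("no region labels available", call. = FALSE)
  }
  scopes <- c("nationwide", sort(unique(unname(region_of))))
  out <- list()
  fits <- list()
  for (sc in scopes) {
    if (sc == "nationwide") {
      g <- graph
      pan <- panel
    } else {
      ids <- names(region_of)[region_of == sc]
      if (length(ids) < min_counties) {
        warning("region ", sc, " has fewer than ", min_counties,
                " counties; skipped", call. = FALSE)
        next
      }
      g <- subgraph(graph, ids)
      pan <- panel[panel$county_id %in% ids, ]
    }
    pooled <- stats::setNames(
      vector("list", length(spec$covariates)), spec$covariates
    )
    for (ci in seq_along(covariates)) {
      fit <- fit_hbstm(pan, g, covariates = covariates[[ci]], spec = spec, ...)
      if (sc == "nationwide") fits[[ci]] <- fit
      for (cv in spec$covariates) {
        pooled[[cv]] <- c(pooled[[cv]], fit$draws$beta[, cv])
      }
    }
    eff <- dplyr::bind_rows(lapply(spec$covariates, function(cv) {
      rr_summary(pooled[[cv]], covariate = cv)
    }))
    eff$region <- sc
    out[[sc]] <- eff
  }
  res <- dplyr::bind_rows(out)
  res <- dplyr::select(res, "region", dplyr::everything())
  attr(res, "fits") <- fits
  res
}
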