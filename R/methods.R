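#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
print.hbstm_fit <- function(x, ...) {
  cat(sprintf(
    "<hbstm_fit: %d counties x %d years, %d draws (%d chain%s)>\n",
    length(x$data$county_id), length(x$data$years), length(x$draws$alpha),
    x$mcmc$chains, if (x$mcmc$chains == 1) "" else "s"
  ))
  print(tidy(x), n = 8)
  invisible(x)
}

#' Tidy posterior summaries of a fitted spatiotemporal model
#'
#' @param x An `hbstm_fit`.
#' @param effects Which block to summarise: `"fixed"` (intercept, slope,
#'   coefficients and random-effect standard deviations), `"county"`
#'   (`s`, `u`, `b1` per county) or `"year"` (`v` per year).
#' @param conf_level Credible-interval mass (default 0.95).
#' @param ... Unused.
#' @return A tibble with `term`, `estimate` (posterior median),
#'   `conf.low`, `conf.high` and, for fixed effects, `rhat` and `ess`.
#' @method tidy hbstm_fit
#' @export
tidy.hbstm_fit <- function(x, effects = c("fixed", "county", "year"),
                           conf_level = 0.95, ...) {
  effects <- match.arg(effects)
  pr <- c((1 - conf_level) / 2, 0.5, 1 - (1 - conf_level) / 2)
  qs <- function(v) stats::quantile(v, pr, names = FALSE)
  d <- x$draws
  if (effects == "fixed") {
    cols <- list(alpha = d$alpha)
    if (length(x$data$tvec) > 1) cols$b0 <- d$b0
    for (k in colnames(d$beta)) cols[[paste0("beta_", k)]] <- d$beta[, k]
    for (k in colnames(d$sd)) {
      if (stats::sd(d$sd[, k]) > 0) cols[[paste0("sd_", k)]] <- d$sd[, k]
    }
    out <- dplyr::bind_rows(lapply(names(cols), function(nm) {
      q <- qs(cols[[nm]])
      tibble::tibble(term = nm, estimate = q[2], conf.low = q[1],
                     conf.high = q[3])
    }))
    dplyr::left_join(out, x$diagnostics,
                     by = c(term = "parameter"))
  } else if (effects == "county") {
    dplyr::bind_rows(lapply(c("s", "u", "b1"), function(nm) {
      mat <- d[[nm]]
      tibble::tibble(
        term = nm, county_id = x$data$county_id,
        estimate = apply(mat, 2, stats::median),
        conf.low = apply(mat, 2, stats::quantile, pr[1]),
        conf.high = apply(mat, 2, stats::quantile, pr[3])
      )
    }))
  } else {
    tibble::tibble(
      term = "v", year = x$data$years,
      estimate = apply(d$v, 2, stats::median),
      conf.low = apply(d$v, 2, stats::quantile, pr[1]),
      conf.high = apply(d$v, 2, stats::quantile, pr[3])
    )
  }
}

#' One-row summary of a fitted spatiotemporal model
#'
#' @param x An `hbstm_fit`.
#' @param ... Unused.
#' @return A tibble with the problem size, MCMC settings, mean posterior
#'   log-likelihood, and the worst-case convergence diagnostics.
#' @method glance hbstm_fit
#' @export
glance.hbstm_fit <- function(x, ...) {
  tibble::tibble(
    n_counties = length(x$data$county_id),
    n_years = length(x$data$years),
    n_draws = length(x$draws$alpha),
    chains = x$mcmc$chains,
    mean_loglik = mean(x$draws$loglik),
    max_rhat = max(x$diagnostics$rhat, na.rm = TRUE),
    min_ess = min(x$diagnostics$ess, na.rm = TRUE)
  )
}

#' Plot the fitted national temporal trend
#'
#' Posterior median and credible band of the overall temporal relative risk
#' `exp(b0 * t + v_t)` by year.
#'
#' @param object An `hbstm_fit`.
#' @param conf_level Credible mass (default 0.95).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hbstm_fit
#' @export
autoplot.hbstm_fit <- function(object, conf_level = 0.95, ...) {
  d <- object$draws
  trend <- exp(outer(d$b0, object$data$tvec) + d$v)
  pr <- c((1 - conf_level) / 2, 0.5, 1 - (1 - conf_level) / 2)
  df <- tibble::tibble(
    year = object$data$years,
    lo = apply(trend, 2, stats::quantile, pr[1]),
    mid = apply(trend, 2, stats::median),
    hi = apply(trend, 2, stats::quantile, pr[3])
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$year, y = .data$mid)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::labs(x = "year", y = "temporal relative risk",
                  title = "Overall temporal trend") +
    ggplot2::theme_minimal()
}

#' Map the risk classification on a lattice geography
#'
#' Tile map of the nine-category classification when the graph's nodes
#' carry `row`/`col` coordinates; otherwise a bar chart of category counts.
#'
#' @param object A `risk_classification`.
#' @param graph Optional `county_graph` providing lattice coordinates.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot risk_classification
#' @export
autoplot.risk_classification <- function(object, graph = NULL, ...) {
  if (!is.null(graph) && !is.null(graph$nodes$row)) {
    df <- dplyr::left_join(tibble::as_tibble(object),
                           graph$nodes, by = "county_id")
    ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                     fill = .data$stage1,
                                     alpha = .data$p_spatial)) +
      ggplot2::geom_tile(color = "white") +
      ggplot2::scale_y_reverse() +
      ggplot2::scale_fill_manual(values = c(hot = "#c0392b", cold = "#2471a3",
                                            warm = "#e8b23c")) +
      ggplot2::labs(title = "County risk classification",
                    fill = "spatial pattern", alpha = "P(RR > 1)") +
      ggplot2::theme_minimal()
  } else {
    df <- dplyr::count(tibble::as_tibble(object), .data$category)
    ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$n)) +
      ggplot2::geom_col() +
      ggplot2::coord_flip() +
      ggplot2::labs(x = NULL, y = "counties") +
      ggplot2::theme_minimal()
  }
}

#' Forest plot of ecological relative risks
#'
#' Point-and-interval display of the `EcoEffect` table by region and
#' covariate, on the relative-risk scale with the null line at 1.
#'
#' @param effects Output of [fit_regional()] (or any tibble with `region`,
#'   `covariate`, `rr`, `rr_lo`, `rr_hi`).
#' @return A ggplot object.
#' @export
plot_eco_effects <- function(effects) {
  ggplot2::ggplot(effects,
                  ggplot2::aes(x = .data$rr, y = .data$covariate,
                               color = .data$region)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2) +
    ggplot2::geom_pointrange(
      ggplot2::aes(xmin = .data$rr_lo, xmax = .data$rr_hi),
      position = ggplot2::position_dodge(width = 0.5)
    ) +
    ggplot2::labs(x = "relative risk (95% credible interval)", y = NULL) +
    ggplot2::theme_minimal()
}
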