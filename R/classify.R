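#' Posterior exceedance probabilities per county
#'
#' `p_spatial` is the posterior probability that the county's overall
#' spatial relative risk exceeds 1, i.e. the fraction of draws with
#' `s_i + u_i > 0`; `p_trend` is the posterior probability that the local
#' slope departure is positive, the fraction of draws with `b1_i > 0`.
#'
#' @param fit An `hbstm_fit`.
#' @param min_draws Warn below this many retained draws (default 100).
#' @return A tibble `county_id`, `p_spatial`, `p_trend`.
#' @export
exceedance_probs <- function(fit, min_draws = 100) {
  d <- fit$draws
  D <- length(d$alpha)
  if (D == 0) stop("no retained draws", call. = FALSE)
  if (D < min_draws) {
    warning("only ", D, " retained draws; exceedance probabilities are noisy",
            call. = FALSE)
  }
  tibble::tibble(
    county_id = fit$data$county_id,
    p_spatial = colMeans(d$s + d$u > 0),
    p_trend = colMeans(d$b1 > 0)
  )
}

#' Two-stage hot/cold/warm-spot classification
#'
#' Stage 1 labels each county by its spatial exceedance probability: hot
#' spot when `p_spatial > 0.8`, cold spot when `p_spatial < 0.2`, warm spot
#' otherwise. Stage 2 labels the local trend by the posterior sign
#' probability of the local slope: `p_trend > 0.8` means the local trend
#' runs above the global trend (with a declining global trend, a weaker
#' local decline), `p_trend < 0.2` below it (a stronger local decline), and
#' anything between counts as approximating the global trend. Boundary
#' values (exactly 0.8 or 0.2) fall to the middle category, as the strict
#' inequalities leave equality unassigned. The combined label is
#' `"<stage1>/<stage2>"`, giving nine categories.
#'
#' @param probs A data frame with `p_spatial` and `p_trend` columns (e.g.
#'   from [exceedance_probs()]), or a numeric vector of spatial
#'   probabilities.
#' @param p_trend Trend probabilities when `probs` is a bare vector.
#' @return The input as a tibble with factor columns `stage1`
#'   (hot/cold/warm), `stage2` and `category` appended; class
#'   `risk_classification`.
#' @export
classify_risk <- function(probs, p_trend = NULL) {
  if (!is.data.frame(probs)) {
    probs <- tibble::tibble(p_spatial = probs, p_trend = p_trend)
  }
  probs <- tibble::as_tibble(probs)
  ps <- probs$p_spatial
  pt <- probs$p_trend
  if (any(ps < 0 | ps > 1 | pt < 0 | pt > 1, na.rm = TRUE) ||
      anyNA(ps) || anyNA(pt)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  stage1 <- factor(
    ifelse(ps > 0.8, "hot", ifelse(ps < 0.2, "cold", "warm")),
    levels = c("hot", "cold", "warm")
  )
  stage2 <- factor(
    ifelse(pt < 0.2, "stronger-decline",
           ifelse(pt > 0.8, "weaker-decline", "approximate")),
    levels = c("stronger-decline", "weaker-decline", "approximate")
  )
  probs$stage1 <- stage1
  probs$stage2 <- stage2
  probs$category <- factor(paste(as.character(stage1), as.character(stage2),
                                 sep = "/"))
  class(probs) <- c("risk_classification", class(probs))
  probs
}

#' Cross-classification table of spatial pattern by local trend
#'
#' Tabulates the nine categories as a 3 x 3 table of counts with row
#' percentages (cell / row total x 100, rounded to 2 decimals), row totals
#' and the share of each stage-1 class among all counties.
#'
#' @param classification A `risk_classification` (or any data frame with
#'   `stage1` and `stage2` factor columns), or a 3 x 3 count matrix with
#'   stage-1 rows (hot, cold, warm) and stage-2 columns — useful when only
#'   published counts are available.
#' @param row_totals Optional named stage-1 row totals to use as the
#'   percentage denominators (e.g. totals as printed in a publication).
#'   When they disagree with the cell sums the rows are flagged in the
#'   `"discrepancy"` attribute; by default the self-consistent cell sums
#'   are used.
#' @return A tibble with one row per stage-1 class: counts and percentages
#'   per stage-2 class, `total`, and `share_pct` of all counties.
#' @export
cross_tabulate <- function(classification, row_totals = NULL) {
  if (is.matrix(classification)) {
    tab <- classification
    rownames(tab) <- rownames(tab) %||% c("hot", "cold", "warm")
  } else {
    s1 <- factor(classification$stage1, levels = c("hot", "cold", "warm"))
    s2 <- factor(classification$stage2,
                 levels = c("stronger-decline", "weaker-decline", "approximate"))
    tab <- unclass(table(s1, s2))
  }
  cell_total <- rowSums(tab)
  denom <- cell_total
  discrepancy <- character(0)
  if (!is.null(row_totals)) {
    denom <- row_totals[rownames(tab)]
    off <- which(denom != cell_total)
    if (length(off)) {
      discrepancy <- sprintf(
        "%s: cells sum to %d but stated total is %d",
        rownames(tab)[off], as.integer(cell_total[off]),
        as.integer(denom[off])
      )
      warning("row totals disagree with cell sums: ",
              paste(discrepancy, collapse = "; "), call. = FALSE)
    }
  }
  grand <- sum(denom)
  pct <- tab / ifelse(denom == 0, 1, denom) * 100
  out <- tibble::tibble(
    stage1 = rownames(tab),
    n_stronger = as.integer(tab[, 1]),
    pct_stronger = round(unname(pct[, 1]), 2),
    n_weaker = as.integer(tab[, 2]),
    pct_weaker = round(unname(pct[, 2]), 2),
    n_approximate = as.integer(tab[, 3]),
    pct_approximate = round(unname(pct[, 3]), 2),
    total = as.integer(denom),
    share_pct = round(unname(denom) / max(grand, 1) * 100, 2)
  )
  attr(out, "discrepancy") <- discrepancy
  out
}

#' Posterior change in county mortality between two years
#'
#' Summarises, per county, the posterior distribution of the change in a
#' rate (typically the county ASMR pushed through the fitted relative
#' risks) between the first and last study years: the posterior median
#' change, the share of counties whose median change is negative, and a
#' display binning of counties by their start-year percentile.
#'
#' @param draws_first,draws_last Draws x county matrices of the rate in the
#'   first and last year (column names are county ids), or a single tidy
#'   data frame via `data` below.
#' @param data Alternative tidy input: a data frame with columns
#'   `county_id`, `draw`, `year`, `value` containing exactly two years.
#' @param bins Number of start-period percentile bins (default 4).
#' @return A list with `counties` (per-county tibble: median change, start
#'   median, percentile bin), `share_negative_pct` (share of counties with
#'   negative median change, percent, 2 decimals) and `n`.
#' @export
change_summary <- function(draws_first = NULL, draws_last = NULL,
                           data = NULL, bins = 4) {
  if (!is.null(data)) {
    yrs <- sort(unique(data$year))
    if (length(yrs) != 2) stop("data must contain exactly two years", call. = FALSE)
    wide <- tidyr::pivot_wider(data, names_from = "year", values_from = "value")
    miss <- wide$county_id[!stats::complete.cases(wide)]
    if (length(miss)) {
      stop("missing year for counties: ", paste(unique(miss), collapse = ", "),
           call. = FALSE)
    }
    f <- tidyr::pivot_wider(data[data$year == yrs[1], ],
                            names_from = "county_id", values_from = "value")
    l <- tidyr::pivot_wider(data[data$year == yrs[2], ],
                            names_from = "county_id", values_from = "value")
    ids <- setdiff(names(f), c("draw", "year"))
    draws_first <- as.matrix(f[, ids])
    draws_last <- as.matrix(l[, ids])
  }
  if (!identical(dim(draws_first), dim(draws_last))) {
    stop("first- and last-year draws must have identical dimensions", call. = FALSE)
  }
  if (is.null(colnames(draws_first))) {
    colnames(draws_first) <- colnames(draws_last) <-
      paste0("county_", seq_len(ncol(draws_first)))
  }
  change <- draws_last - draws_first
  med_change <- unname(apply(change, 2, stats::median))
  start_med <- unname(apply(draws_first, 2, stats::median))
  qs <- unique(stats::quantile(start_med, probs = seq(0, 1, length.out = bins + 1)))
  bin <- if (length(qs) < 2) {
    rep(1L, length(start_med))
  } else {
    cut(start_med, breaks = qs, include.lowest = TRUE, labels = FALSE)
  }
  counties <- tibble::tibble(
    county_id = colnames(draws_first),
    median_change = med_change,
    start_median = start_med,
    start_percentile_bin = bin
  )
  list(
    counties = counties,
    share_negative_pct = round(mean(med_change < 0) * 100, 2),
    n = ncol(draws_first)
  )
}

#' Range of county rates in a year
#'
#' The gap between the highest- and lowest-rate county, a simple inequality
#' summary.
#'
#' @param values County rates, or a data frame with `year` and `value`
#'   columns (then `year` selects the rows).
#' @param year Year filter for data-frame input.
#' @return `max - min` (scalar).
#' @examples
#' asmr_gap(c(479.19, 163.57, 200.0)) # 315.62
#' @export
asmr_gap <- function(values, year = NULL) {
  if (is.data.frame(values)) {
    if (!is.null(year)) values <- values[values$year == year, ]
    values <- values$value
  }
  if (!length(values)) stop("no county values supplied", call. = FALSE)
  max(values) - min(values)
}

#' Posterior draws of county ASMR from a fitted model
#'
#' Under indirect standardization with shared reference rates, every age-sex
#' stratum of a county scales by the same relative risk `theta_it`, so the
#' county's directly standardized rate is `theta_it` times the reference
#' ASMR (the census-weighted reference rate). This pushes the posterior of
#' the fitted risks onto the ASMR scale per draw.
#'
#' @param fit An `hbstm_fit`.
#' @param reference_asmr The reference population's age-standardized rate
#'   (same scale as the desired output, e.g. per 100,000).
#' @param years Years to include (default all).
#' @return A draws x county x year array of ASMRs.
#' @export
asmr_draws <- function(fit, reference_asmr, years = NULL) {
  theta_draws(fit, years = years) * reference_asmr
}

#' Census-weighted reference ASMR of a panel
#'
#' The age-standardized rate of the pooled reference population implied by
#' the panel's own stratum rates — the constant that converts fitted
#' relative risks to the ASMR scale in [asmr_draws()]. Sexes are combined
#' by their population shares within each age band.
#'
#' @param panel A `CountyPanel` with `sex`, `age_group`, `population` and a
#'   deaths column.
#' @param weights Census weights tibble (`age_group`, `weight`).
#' @param deaths_col Deaths column to use.
#' @param per Output scale (default per 100,000).
#' @return Scalar reference ASMR.
#' @export
reference_asmr <- function(panel, weights, deaths_col = "deaths_cvd",
                           per = 1e5) {
  rates <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(panel), .data$age_group),
    rate = sum(.data[[deaths_col]]) / sum(.data$population),
    .groups = "drop"
  )
  asmr(rates, weights) * per
}
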