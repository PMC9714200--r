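#' Under-reporting adjustment of reported death counts
#'
#' Inverts the registry's missingness: when a fraction `urr` of deaths is
#' missed, the adjusted count is `reported / (1 - urr)`. Vectorised over
#' both arguments.
#'
#' @param reported Reported death counts (non-negative).
#' @param urr Under-reporting rate(s) in `[0, 1)`.
#' @return Adjusted death counts (non-negative reals).
#' @examples
#' adjust_underreporting(90, 0.10) # 100
#' @export
adjust_underreporting <- function(reported, urr) {
  if (any(urr < 0 | urr >= 1, na.rm = TRUE)) {
    stop("urr must lie in [0, 1)", call. = FALSE)
  }
  if (any(reported < 0, na.rm = TRUE)) {
    stop("reported counts must be non-negative", call. = FALSE)
  }
  reported / (1 - urr)
}

#' Apply under-reporting adjustment cell-wise to a panel
#'
#' Joins the stratum-year URR schedule onto the panel and divides the
#' reported counts by `1 - URR`, producing `deaths_all_adj` and
#' `deaths_cvd_adj` columns. Cells whose stratum-year is missing from the
#' schedule raise an error listing the missing keys.
#'
#' @param panel A `CountyPanel` with `region`, `urban`,
#'   `deaths_all_reported` and `deaths_cvd_reported` columns (falls back to
#'   `deaths_all` / `deaths_cvd` when reported columns are absent).
#' @param urr_schedule Tibble with `region`, `urban`, `year`, `urr`.
#' @return The panel with adjusted-count columns appended.
#' @export
adjust_panel <- function(panel, urr_schedule) {
  panel <- tibble::as_tibble(panel)
  rep_all <- panel$deaths_all_reported %||% panel$deaths_all
  rep_cvd <- panel$deaths_cvd_reported %||% panel$deaths_cvd
  key <- dplyr::left_join(panel[, c("region", "urban", "year")],
                          urr_schedule, by = c("region", "urban", "year"))
  if (anyNA(key$urr)) {
    miss <- unique(key[is.na(key$urr), c("region", "urban", "year")])
    stop("URR schedule missing for stratum-years: ",
         paste(sprintf("%s/%s/%d", miss$region,
                       ifelse(miss$urban, "urban", "rural"), miss$year),
               collapse = "; "),
         call. = FALSE)
  }
  panel$deaths_all_adj <- adjust_underreporting(rep_all, key$urr)
  panel$deaths_cvd_adj <- adjust_underreporting(rep_cvd, key$urr)
  panel
}

#' Extrapolate an under-reporting schedule to later years
#'
#' Field surveys provide URR only up to some year; later years are predicted
#' per stratum by a least-squares spline on calendar year — a natural cubic
#' spline with interior knots at the observed-year quartiles when six or
#' more years are observed, degenerating to a straight line below that.
#' Predictions are clamped to `[0, 0.95]` so the adjustment factor
#' `1/(1-URR)` stays bounded. Strata with fewer than four observed years
#' carry the last observed value forward with a warning.
#'
#' @param urr_schedule Tibble with `region`, `urban`, `year`, `urr` (observed
#'   years only).
#' @param to_year Extend the schedule through this year.
#' @return The schedule with predicted years appended and a logical
#'   `extrapolated` column.
#' @export
extrapolate_urr <- function(urr_schedule, to_year = 2020) {
  urr_schedule <- tibble::as_tibble(urr_schedule)
  out <- dplyr::group_modify(
    dplyr::group_by(urr_schedule, .data$region, .data$urban),
    function(d, g) {
      d <- dplyr::arrange(d, .data$year)
      new_years <- setdiff(seq(min(d$year), to_year), d$year)
      new_years <- new_years[new_years > max(d$year)]
      if (!length(new_years)) {
        d$extrapolated <- FALSE
        return(d)
      }
      if (nrow(d) < 4) {
        warning("stratum ", g$region, "/", ifelse(g$urban, "urban", "rural"),
                " has <4 observed years; carrying last URR forward",
                call. = FALSE)
        pred <- rep(d$urr[nrow(d)], length(new_years))
      } else {
        if (nrow(d) >= 6) {
          knots <- stats::quantile(d$year, c(0.25, 0.5, 0.75))
          basis <- splines_ns(d$year, knots, range(d$year))
          fit <- stats::lm.fit(cbind(1, basis), d$urr)
          newb <- splines_ns(new_years, knots, range(d$year))
          pred <- as.numeric(cbind(1, newb) %*% fit$coefficients)
        } else {
          fit <- stats::lm.fit(cbind(1, d$year), d$urr)
          pred <- as.numeric(cbind(1, new_years) %*% fit$coefficients)
        }
      }
      pred <- pmin(0.95, pmax(0, pred))
      dplyr::bind_rows(
        dplyr::mutate(d, extrapolated = FALSE),
        tibble::tibble(year = as.integer(new_years), urr = pred,
                       extrapolated = TRUE)
      )
    }
  )
  dplyr::ungroup(out)
}

# Natural cubic spline basis with fixed boundary knots; linear extrapolation
# beyond the boundary (the defining property of the natural spline), which is
# what makes out-of-range URR prediction stable.
splines_ns <- function(x, knots, boundary) {
  splines::ns(x, knots = knots, Boundary.knots = boundary)
}

#' Exclude seriously under-reported counties
#'
#' Computes each county-year's crude adjusted all-cause mortality rate
#' (adjusted all-cause deaths over population, in deaths per 1,000) and
#' drops counties whose rate falls below the applicable completeness
#' threshold in at least `min_failing_years` years. Surveillance-system
#' counties are held to 4.5 per 1,000 before 2013 and 5 per 1,000 from 2013
#' on; counties outside the surveillance systems to 3 per 1,000 in all
#' years.
#'
#' @param panel A `CountyPanel` with `deaths_all_adj` (see [adjust_panel()]).
#' @param surveillance Either a logical vector/tibble mapping `county_id` to
#'   a surveillance flag, or a single logical recycled to all counties.
#' @param min_failing_years Number of failing years that triggers exclusion
#'   (default 1).
#' @return A list with `panel` (retained counties, unchanged rows) and
#'   `exclusions`, a log tibble with one row per excluded county naming the
#'   rule, the offending years and the threshold.
#' @export
apply_quality_filters <- function(panel, surveillance, min_failing_years = 1) {
  panel <- tibble::as_tibble(panel)
  if (is.null(panel$deaths_all_adj)) {
    stop("panel lacks deaths_all_adj; run adjust_panel() first", call. = FALSE)
  }
  ids <- unique(panel$county_id)
  if (is.data.frame(surveillance)) {
    flag <- surveillance$surveillance[match(ids, surveillance$county_id)]
  } else if (length(surveillance) == 1) {
    flag <- rep(as.logical(surveillance), length(ids))
  } else {
    flag <- as.logical(surveillance)[match(ids, names(surveillance))]
  }
  if (anyNA(flag)) {
    stop("unknown surveillance flag for counties: ",
         paste(ids[is.na(flag)], collapse = ", "), call. = FALSE)
  }
  cy <- dplyr::summarise(
    dplyr::group_by(panel, .data$county_id, .data$year),
    rate_permille = sum(.data$deaths_all_adj) / sum(.data$population) * 1000,
    .groups = "drop"
  )
  cy$surveillance <- flag[match(cy$county_id, ids)]
  cy$threshold <- ifelse(cy$surveillance,
                         ifelse(cy$year >= 2013, 5, 4.5), 3)
  cy$fails <- cy$rate_permille < cy$threshold
  bad <- dplyr::summarise(
    dplyr::group_by(cy, .data$county_id),
    n_failing = sum(.data$fails),
    offending_years = paste(.data$year[.data$fails], collapse = ","),
    threshold = paste(unique(.data$threshold[.data$fails]), collapse = ","),
    .groups = "drop"
  )
  bad <- bad[bad$n_failing >= min_failing_years, ]
  exclusions <- tibble::tibble(
    county_id = bad$county_id,
    rule = ifelse(flag[match(bad$county_id, ids)],
                  "surveillance_completeness", "nonsurveillance_completeness"),
    offending_years = bad$offending_years,
    threshold_permille = bad$threshold
  )
  list(
    panel = panel[!panel$county_id %in% exclusions$county_id, ],
    exclusions = exclusions
  )
}

#' Cause-specific rate from an all-cause rate and a cause fraction
#'
#' The CVD mortality rate for a stratum is the all-cause mortality rate
#' times the proportion of deaths with CVD as underlying cause. Strata with
#' zero all-cause deaths get rate 0 (there is no cause information to
#' apportion) and are flagged via the `"zero_denominator"` attribute.
#'
#' @param all_cause_rate All-cause mortality rate (any consistent scale).
#' @param deaths_cvd,deaths_all Death counts; `deaths_cvd <= deaths_all`.
#' @return The CVD rate on the same scale as `all_cause_rate`.
#' @examples
#' cvd_rate(0.010, 40, 100) # 0.004
#' @export
cvd_rate <- function(all_cause_rate, deaths_cvd, deaths_all) {
  if (any(deaths_cvd > deaths_all, na.rm = TRUE)) {
    stop("deaths_cvd must not exceed deaths_all", call. = FALSE)
  }
  out <- ifelse(deaths_all == 0, 0,
                all_cause_rate * deaths_cvd / pmax(deaths_all, 1e-300))
  zero <- which(deaths_all == 0)
  if (length(zero)) attr(out, "zero_denominator") <- zero
  out
}

#' Direct age standardization
#'
#' Weighted sum of age-specific rates using fixed census weights; output is
#' on the same scale as the input rates (feed per-100,000 rates to get a
#' per-100,000 ASMR).
#'
#' @param rates Age-specific rates, either a numeric vector named or ordered
#'   by age group, or a tibble with `age_group` and `rate` columns.
#' @param weights A tibble with `age_group` and `weight` columns; weights
#'   must be non-negative and sum to 1.
#' @return The age-standardized rate (scalar).
#' @examples
#' w <- tibble::tibble(age_group = c("young", "old"), weight = c(0.5, 0.5))
#' asmr(c(young = 100, old = 300), w) # 200
#' @export
asmr <- function(rates, weights) {
  if (is.data.frame(rates)) {
    r <- rates$rate
    names(r) <- rates$age_group
    rates <- r
  }
  if (abs(sum(weights$weight) - 1) > 1e-9 || any(weights$weight < 0)) {
    stop("weights must be non-negative and sum to 1", call. = FALSE)
  }
  if (!is.null(names(rates))) {
    miss <- setdiff(weights$age_group, names(rates))
    if (length(miss)) {
      stop("missing age stratum: ", paste(miss, collapse = ", "), call. = FALSE)
    }
    rates <- rates[match(weights$age_group, names(rates))]
  } else if (length(rates) != nrow(weights)) {
    stop("rates and weights must share the age index", call. = FALSE)
  }
  sum(weights$weight * rates)
}

#' Average annual percent change of a rate series
#'
#' Summarises a trend as the constant yearly percentage change implied by a
#' log-linear fit: the least-squares slope `b` of `ln(rate)` on year gives
#' `AAPC = (exp(b) - 1) * 100`. The `"endpoint"` method instead uses only
#' the first and last values, `((last/first)^(1/(n_years)) - 1) * 100` —
#' the two agree exactly for a geometric series.
#'
#' @param rates Positive rate values (e.g. yearly ASMRs).
#' @param years Calendar years, same length as `rates`.
#' @param method `"regression"` (default, all years) or `"endpoint"`.
#' @return Percent change per year (scalar).
#' @examples
#' aapc(c(100, 99, 98.01), 2000:2002) # -1
#' @export
aapc <- function(rates, years = seq_along(rates), method = c("regression", "endpoint")) {
  method <- match.arg(method)
  if (length(rates) < 2) stop("need at least 2 years", call. = FALSE)
  if (any(rates <= 0)) stop("rates must be positive for a log-scale trend", call. = FALSE)
  if (length(years) != length(rates)) stop("years and rates differ in length", call. = FALSE)
  if (method == "regression") {
    b <- stats::cov(years, log(rates)) / stats::var(years)
  } else {
    span <- years[length(years)] - years[1]
    b <- log(rates[length(rates)] / rates[1]) / span
  }
  (exp(b) - 1) * 100
}

`%||%` <- function(a, b) if (is.null(a)) b else a
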