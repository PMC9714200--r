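#' Read and write the standard CSV schemas
#'
#' Thin wrappers around readr with the column types pinned, so round trips
#' reproduce integers exactly and reals to full double precision. The panel
#' schema is `county_id, year, sex, age_group, population, deaths_all,
#' deaths_cvd, deaths_cvd_reported` (extra columns pass through).
#'
#' @param path File path.
#' @param x Tibble to write.
#' @return Readers return tibbles; writers return `path` invisibly.
#' @name mortmap_io
NULL

#' @rdname mortmap_io
#' @export
read_panel <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("county_id", "year", "population")
  miss <- setdiff(need, names(out))
  if (length(miss)) {
    stop("panel file ", path, " lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  out$county_id <- as.character(out$county_id)
  out
}

#' @rdname mortmap_io
#' @export
write_panel <- function(x, path) {
  readr::write_csv(x, path, progress = FALSE)
  invisible(path)
}

#' @rdname mortmap_io
#' @export
read_urr <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("region", "urban", "year", "urr")
  miss <- setdiff(need, names(out))
  if (length(miss)) {
    stop("URR file ", path, " lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (any(out$urr < 0 | out$urr >= 1)) {
    stop("URR values in ", path, " must lie in [0, 1)", call. = FALSE)
  }
  out
}

#' @rdname mortmap_io
#' @export
read_weights <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("age_group", "weight") %in% names(out))) {
    stop("weights file ", path, " needs age_group and weight columns",
         call. = FALSE)
  }
  if (abs(sum(out$weight) - 1) > 1e-9) {
    stop("weights in ", path, " must sum to 1", call. = FALSE)
  }
  out
}

#' Run the full synthetic-study pipeline
#'
#' Chains the package end to end: simulate a county study, adjust the
#' reported counts for under-reporting, apply the completeness filters,
#' fit the spatiotemporal model, classify counties, and (optionally) run
#' the ecological regression. Every artifact is written under `out_dir`
#' along with a JSON manifest recording the seed, configuration hash,
#' per-stage row accounting and output files. The same config and seed
#' reproduce identical outputs.
#'
#' @param config A list (or YAML file path) with optional entries `sim`
#'   (arguments to [sim_config()]), `mcmc` (`iterations`, `burn_in`,
#'   `thin`, `chains`), `eco` (`TRUE`/`FALSE`, default `TRUE`), and
#'   `min_failing_years`.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed overriding `config$sim$seed`.
#' @return The manifest (invisibly a list; written as `manifest.json`).
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("mortmap_run_"),
                         seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stage <- "configure"
  manifest <- list(stages = list(), files = character())
  res <- tryCatch({
    sim_args <- config$sim %||% list()
    if (!is.null(seed)) sim_args$seed <- seed
    cfg <- do.call(sim_config, sim_args)
    manifest$seed <- cfg$seed
    manifest$config_hash <- rlang::hash(list(config, cfg$seed))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

    stage <- "simulate"
    sim <- simulate_panel(cfg)
    write_panel(sim$panel, file.path(out_dir, "panel.csv"))
    write_edge_list(sim$graph, file.path(out_dir, "graph.edges"))
    readr::write_csv(sim$urr, file.path(out_dir, "urr.csv"), progress = FALSE)
    readr::write_csv(sim$weights, file.path(out_dir, "weights.csv"),
                     progress = FALSE)
    readr::write_csv(sim$covariates, file.path(out_dir, "covariates.csv"),
                     progress = FALSE)
    manifest$stages$simulate <- list(
      counties = n_counties(sim$graph), cells = nrow(sim$panel)
    )

    stage <- "preprocess"
    panel <- adjust_panel(sim$panel, sim$urr)
    filt <- apply_quality_filters(panel, surveillance = TRUE,
                                  min_failing_years =
                                    config$min_failing_years %||% 1)
    readr::write_csv(filt$exclusions, file.path(out_dir, "exclusions.csv"),
                     progress = FALSE)
    n_in <- length(unique(panel$county_id))
    n_out <- length(unique(filt$panel$county_id))
    manifest$stages$preprocess <- list(
      counties_in = n_in, counties_excluded = n_in - n_out,
      counties_out = n_out
    )
    graph <- subgraph(sim$graph, unique(filt$panel$county_id))

    stage <- "fit"
    mc <- config$mcmc %||% list()
    fit <- fit_hbstm(
      filt$panel, graph,
      spec = hbstm_spec(),
      iterations = mc$iterations %||% 2000,
      burn_in = mc$burn_in %||% 500,
      thin = mc$thin %||% 2,
      chains = mc$chains %||% 1,
      seed = cfg$seed,
      deaths_col = "deaths_cvd_adj"
    )
    readr::write_csv(tidy(fit), file.path(out_dir, "fit_fixed.csv"),
                     progress = FALSE)
    readr::write_csv(tidy(fit, effects = "county"),
                     file.path(out_dir, "fit_county.csv"), progress = FALSE)
    manifest$stages$fit <- as.list(glance(fit))

    stage <- "classify"
    cls <- classify_risk(exceedance_probs(fit))
    readr::write_csv(tibble::as_tibble(cls),
                     file.path(out_dir, "classification.csv"),
                     progress = FALSE)
    tab <- cross_tabulate(cls)
    readr::write_csv(tab, file.path(out_dir, "cross_tab.csv"),
                     progress = FALSE)
    ref <- reference_asmr(filt$panel, sim$weights,
                          deaths_col = "deaths_cvd_adj")
    ad <- asmr_draws(fit, ref, years = range(fit$data$years))
    chg <- change_summary(ad[, , 1], ad[, , 2])
    readr::write_csv(chg$counties, file.path(out_dir, "change_summary.csv"),
                     progress = FALSE)
    manifest$stages$classify <- list(
      hot = sum(cls$stage1 == "hot"), cold = sum(cls$stage1 == "cold"),
      warm = sum(cls$stage1 == "warm"),
      share_negative_pct = chg$share_negative_pct
    )

    if (isTRUE(config$eco %||% TRUE)) {
      stage <- "eco"
      covs <- standardize_covariates(sim$covariates)
      eco_spec <- hbstm_spec(
        covariates = c("GDP", "NTL", "NB", "PD"),
        confounders = intersect(c("TEMP", "TV", "HUMID", "LT", "AT", "PM25"),
                                names(covs))
      )
      eco <- fit_regional(
        filt$panel, graph, covs, eco_spec,
        iterations = mc$iterations %||% 2000,
        burn_in = mc$burn_in %||% 500,
        thin = mc$thin %||% 2,
        seed = cfg$seed, deaths_col = "deaths_cvd_adj"
      )
      readr::write_csv(eco, file.path(out_dir, "eco_effects.csv"),
                       progress = FALSE)
      manifest$stages$eco <- list(rows = nrow(eco))
    }

    manifest$files <- list.files(out_dir)
    manifest
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  jsonlite::write_json(res, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(res)
}
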