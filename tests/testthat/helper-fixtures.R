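# Small fixtures shared across test files; everything is generated in code.

tiny_config <- function(seed = 1, ...) {
  sim_config(n_rows = 4, n_cols = 4, years = 2006:2010, seed = seed, ...)
}

# A 3-county path graph: the smallest graph with a non-trivial CAR structure.
path3 <- function() {
  county_graph(
    nodes = tibble::tibble(county_id = c("a", "b", "c")),
    edges = tibble::tibble(from = c("a", "b"), to = c("b", "c"))
  )
}

# Hand-built two-county, two-age panel for standardization oracles.
two_county_panel <- function() {
  tibble::tibble(
    county_id = rep(c("a", "b"), each = 4),
    year = rep(rep(2006:2007, each = 2), 2),
    age_group = rep(c("young", "old"), 4),
    population = c(1000, 500, 1000, 500, 2000, 1000, 2000, 1000),
    deaths_cvd = c(2, 10, 3, 12, 4, 20, 5, 24)
  )
}
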