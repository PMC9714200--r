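Package: mortmap
Title: Hierarchical Bayesian Spatiotemporal Mapping of Small-Area Mortality
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for county-level disease-mapping studies of mortality
    registry data: under-reporting adjustment and data-quality filtering of
    death counts, direct and indirect standardization (ASMR, SMR, expected
    counts), a hierarchical Bayesian spatiotemporal Poisson model with
    BYM-type spatial effects, spatially correlated local time trends and a
    built-in adaptive Metropolis-within-Gibbs sampler, exceedance-probability
    hot/cold/warm-spot classification, and ecological regression of area-level
    nonmedical determinants reported as relative risks with credible
    intervals. Includes a synthetic-data generator that draws county
    geographies, populations and death counts from the model's own generative
    process so every stage of the pipeline can be exercised end to end
    without access to restricted registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    readr,
    rlang,
    splines,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
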