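Package: soycansim
Title: Soybean Canopy Photosynthesis Simulation and Photosynthetic
    Parameter Sensitivity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A mechanistic soybean canopy photosynthesis and growth
    simulator together with the sensitivity machinery needed to ask how
    much crop assimilation and yield respond to changes in the two
    headline photosynthetic capacities, the maximum Rubisco carboxylation
    rate (Vcmax) and the maximum electron transport rate (Jmax). The leaf
    model is the steady-state Farquhar-von Caemmerer-Berry (FvCB) scheme
    coupled to Ball-Berry stomatal conductance; leaves are integrated
    over a multilayer sunlit/shaded canopy, and hourly canopy carbon
    gain drives photothermal development and logistic biomass
    partitioning into leaf, stem, root and pod pools. On top of the
    simulator sit scaling grids over (Vcmax, Jmax) at several CO2
    levels, spline-interpolated response surfaces with gradient-path
    analysis, a day-block bootstrap weather resampler, a synthetic
    multi-year hourly weather generator, and partial rank correlation
    (PRCC) attribution of yield gains to climate drivers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
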