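Package: greenexposure
Title: Population-Weighted Greenspace Exposure, Inequality and Drivers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Multiscale assessment of human exposure to urban greenspace from
    gridded greenspace-fraction and population rasters. Implements fractional
    aggregation of binary greenspace maps, buffered (focal circular-kernel)
    greenspace fractions, physical greenspace coverage, population-weighted
    exposure per administrative zone, population-weighted Lorenz curves and
    Gini indices of exposure inequality, seasonal spatiotemporal variation
    statistics, landscape pattern metrics (patch structure and edge density),
    and driver-attribution statistics (correlation screening, nested OLS
    models, variance inflation factors, and variance partitioning of
    inequality into provision, configuration, joint and residual fractions).
    Ships seed-deterministic synthetic-data generators (spatially
    autocorrelated greenspace fields, clustered population surfaces, seasonal
    phenology stacks, multi-city driver tables) so every stage can be tested
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    pracma,
    igraph,
    withr
Suggests:
    testthat (>= 3.0.0),
    vegan,
    car,
    optparse
Config/testthat/edition: 3
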