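Package: riverlight
Title: Underwater Light Color, Directional Connectivity, and Phytoplankton
    Community Structure in Riverscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for riverscape bio-optics and spatial community analysis:
    quanta-integrated waveband irradiance and diffuse attenuation (Kd) from
    hyperspectral depth profiles, underwater color ratios and photic-zone
    metrics, CDOM absorption coefficients, structural riverscape indices
    (mean depth, confluence density, tributary hydrological index),
    asymmetric eigenvector maps (AEM) built from a directional station
    graph with seeded forward selection, Box-Cox/VIF preprocessing,
    exhaustive best-subsets regression ranked by AIC, two-table variation
    partitioning between spatial and environmental predictors, and exact
    lmg hierarchical relative importance. A seeded synthetic river
    generator (network, tributary mixing, optical fields, light profiles,
    and a phytoplankton response to color ratio and nutrients) makes every
    stage testable without field data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    knitr,
    MASS,
    rmarkdown,
    testthat (>= 3.0.0),
    vegan,
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
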