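Package: rangebridge
Title: Dynamic Brownian Bridge Home Ranges for Radio-Telemetry Tracks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimation and comparison of animal home ranges from
    time-stamped relocation tracks. Implements Brownian bridge movement
    models with a constant motion variance (BBMM) and the dynamic variant
    (dBBMM) in which the Brownian motion variance is estimated in sliding
    windows with change-point model selection, alongside minimum convex
    polygons and fixed kernel density estimators with reference,
    least-squares cross-validation, plug-in and manual bandwidths. Provides
    shared reference grids, utilization-distribution isopleths with
    area/perimeter/complexity metrics, AUC-based estimator evaluation,
    Manly habitat selection ratios, seasonal analyses, a state-switching
    synthetic telemetry generator with patchy habitat rasters, and a
    configuration-driven pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    withr,
    stats,
    grDevices,
    KernSmooth,
    generics
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
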