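Package: capkinetics
Title: Kinetics of Capillary Blood Flow Responses to Local Gas Challenges
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of capillary hemodynamic responses to step
    changes in local oxygen and carbon dioxide concentration. Provides gas-challenge
    protocol definitions, a synthetic generator of per-capillary second-by-second
    hemodynamics (red blood cell velocity, lineal density, hematocrit, supply rate
    and oxygen saturation) with known ground truth, an optional dual-wavelength
    space-time image (kymograph) forward model with matching velocimetry, cell
    counting and ratiometric oximetry estimators, constrained delayed mono- and
    bi-exponential non-linear least-squares kinetics fitting with R-squared, and
    baseline-referenced Dunnett-adjusted onset and peak statistics, orchestrated by
    a reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    mvtnorm,
    pracma,
    jsonlite,
    yaml,
    tibble,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr,
    optparse
Config/testthat/edition: 3
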