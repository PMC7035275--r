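Package: stemflux
Title: Chamber-Based Soil and Tree Stem Greenhouse Gas Flux Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating methane and nitrous oxide fluxes from
    closed-chamber headspace concentration time series, covering manual
    static stem chambers sampled by gas chromatography and automated
    dynamic soil chambers monitored by a high-frequency gas analyser.
    Implements ideal-gas conversion from mole fraction to mass
    concentration, windowed linear flux fitting with a carbon-dioxide
    R-squared quality gate, exponential flux-versus-stem-height profile
    models, cylindrical stem-area-index upscaling to ground area,
    stem-versus-soil flux partitioning, cumulative period budgets, and a
    fully seeded synthetic campaign generator for end-to-end validation
    of the pipeline against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    minpack.lm,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
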