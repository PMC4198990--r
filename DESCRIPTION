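Package: hybridex
Title: Hybrid Dispersion and Kriged-Background Modeling of Near-Road Air
    Pollution Exposure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Estimates ambient exposure to traffic-related air pollutants by
    combining local-scale steady-state Gaussian dispersion (road links as line
    sources, stacks as buoyant point sources, gridded area sources) with a
    regional background obtained by space-time ordinary kriging of monitor
    observations scaled by a regional-fraction field. Hourly concentrations
    are evaluated on anonymizing near-road receptor mini-grids, interpolated
    to home locations, and reduced to windowed, source-apportioned exposure
    metrics with model-to-monitor evaluation statistics. Includes a synthetic
    scenario generator with known ground truth so every stage of the pipeline
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
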