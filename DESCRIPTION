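Package: upwellr
Title: Interannual Productivity Variability Analysis for Eastern Boundary
    Upwelling Systems
Version: 0.1.0
Authors@R:
    person("Artifact", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing interannual variability of net primary
    production (NPP) and sea surface temperature in coastal upwelling
    systems from monthly gridded fields: pointwise detrending and
    deseasonalization, threshold-and-duration extreme-event detection on
    region-mean anomaly series, lag composites with a nonparametric
    bootstrap (resampling without replacement) significance test, mixed
    layer heat-budget bookkeeping with a Q'/H' decomposition of the
    air-sea flux storage term, climate index construction (AMV,
    Nino3.4/ONI) with sliding-window Pearson correlations, and coastal
    Hovmoeller diagrams with FFT high-pass and 1-2-1 filtering for
    coastal-trapped-wave signatures. A synthetic-data generator with
    recorded ground truth (trends, seasonal cycles, AR(1) noise, injected
    events, a propagating coastal sea-level pulse, and heat-budget terms
    that close by construction) provides a download-free test surface for
    every stage, orchestrated by a deterministic end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
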