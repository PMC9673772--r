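Package: canopylux
Title: Macroalgal Canopy Biomass Monitoring from Paired Light Loggers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates seasonal macroalgal canopy biomass from paired
    under-canopy and open-rock light loggers. The log ratio of open to
    under-canopy illuminance is a Beer-Lambert attenuation index that
    cancels surface light, water depth and water-column turbidity,
    leaving the product of the canopy attenuation coefficient and the
    thallus area index. The package ingests logger CSV exports, applies
    solar-geometry based night and crepuscular filters, extracts the
    seasonal biomass trend with a LOESS smoother, converts the index to
    thallus area index given a canopy attenuation coefficient, checks
    sensor drift against a reference radiation series, and includes a
    synthetic intertidal light-climate simulator for end-to-end
    validation by parameter recovery.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    optparse
Config/testthat/edition: 3
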