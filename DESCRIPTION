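Package: cgrvar
Title: Tropical Extreme Droughts and the Variability of the Atmospheric
    CO2 Growth Rate
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to analyse the long-term variability of the atmospheric
    CO2 growth rate (CGR) and its apparent climate sensitivities, and to
    relate both to the tropical land area affected by extreme meteorological
    drought. Implements moving-window multivariate sensitivity regressions
    (nine competing model structures with AIC, adjusted R2 and variance
    inflation diagnostics, plus bootstrap coefficient uncertainty),
    percentile-based drought classification of gridded monthly
    precipitation with frequency- and area-weighted drought-area series,
    Durbin-Watson and Cochrane-Orcutt autocorrelation diagnostics and
    corrections, windowed standard-deviation (STD) series, STD-versus-
    drought-area attribution, and a net-ecosystem-exchange-weighted
    regional partition of STD changes. A seeded synthetic-data generator
    emulates the annual tropical climate system, the CGR series, gridded
    monthly precipitation with nonstationary drought epochs, and region
    masks, so that the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    lmtest,
    car,
    optparse
Config/testthat/edition: 3
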