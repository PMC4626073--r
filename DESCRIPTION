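Package: heatav
Title: Heat-Attributable Emergency Department Visits from Warm-Season Daily Counts
Version: 0.1.0
Authors@R: person("heatav", "maintainers", email = "heatav@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the short-term impact of summer heat on
    emergency department (ED) activity from daily visit counts. Builds
    apparent-temperature exposure series (Kalkstein-Valimont dew-point index,
    lagged-window means, station-averaged PM10, adjacent-day imputation), fits
    Poisson regression heat-response models with a maximum-likelihood
    changepoint (two log-linear segments joined at an estimated threshold,
    with spline-based exploratory fits and age-interaction tests), and
    propagates estimation uncertainty into heat-attributable visit counts via
    Monte Carlo sampling of the slope and threshold, yielding attributable
    totals, attributable community rates and per-day burden summaries. A
    calibrated synthetic-data generator reproduces the statistical structure
    of warm-season ED surveillance data so the whole pipeline is testable
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    splines,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
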