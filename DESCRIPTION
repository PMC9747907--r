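Package: heatptb
Title: Heatwave-Attributable Preterm Birth Burden and Human Capital Losses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An attribution pipeline for estimating the burden of preterm
    births (PTB) caused by heatwave exposure in the final gestational week,
    and the downstream human-capital and economic consequences. Detects
    heatwaves on gridded daily maximum temperature series using a
    percentile-threshold run definition, converts province-level demographic
    tables into daily baseline PTB counts, applies an attributable-fraction
    risk model, and isolates the anthropogenic contribution by differencing
    factual (all-forcings) and counterfactual (natural-forcings-only) climate
    ensembles after quantile-mapping bias correction. Uncertainty in the
    exposure-response relationship is propagated by Monte Carlo sampling of
    the log relative risk. A synthetic-data module generates temperature
    ensembles and internally consistent demographic tables so the whole
    pipeline can be exercised and tested without external climate archives.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
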