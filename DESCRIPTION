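Package: wingtrends
Title: Long-Term Morphometric Trend Analysis for Migratory Shorebirds
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing multi-decade morphometric monitoring series
    of migratory shorebirds, built around five-decade wing- and bill-length
    records of semipalmated sandpipers (Calidris pusilla). Reads annual-mean
    summary tables and individual capture records, applies museum-specimen
    shrinkage corrections and bill-measurement conversions, simulates
    sex-pooled historical baseline distributions from museum sex-group
    statistics and compares them to live samples with replicated resampled
    t-tests, fits linear and quadratic trends to annual means with ANCOVA
    common-slope estimation and pooled period contrasts, computes
    standardized evolutionary rates (darwins, haldanes), and analyses
    bill-wing allometric covariance and its change over time. Includes a
    synthetic-data generator emulating the sampling design (sexual size
    dimorphism, geographic clines, piecewise trends, measurement-method
    offsets, seasonally biased sex ratios) so the whole pipeline is testable
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse,
    withr
Config/testthat/edition: 3
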