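Package: urbancarbon
Title: Urban Organic Carbon Stock Accounting with Monte Carlo Uncertainty
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bookkeeping model for organic carbon stored in urban areas across
    four pools (vegetation of green spaces, soils beneath green and impervious
    surfaces, human bodies, and buildings including construction wood and
    furniture). Provides deterministic per-province point estimates, Monte
    Carlo uncertainty propagation with normal and mean-matched log-normal
    input distributions, one-at-a-time sensitivity analysis, regional and
    national aggregation with carbon densities and pool fractions, a
    storage-area regression with global extrapolation, and a synthetic
    provincial-statistics generator with calibration to published national
    aggregates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
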