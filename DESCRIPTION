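Package: pmgapfill
Title: Gap Filling, Quality Control and Assessment for PM2.5 Time Series
Version: 0.1.0
Authors@R:
    person("Pavlodar", "Air Quality Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for reconstructing hourly PM2.5 exposure time series with
    missing data. Provides a minute-level sensor quality-control pipeline
    (spike and interquartile-range outlier masking, timeline regularization,
    delayed-timestamp correction, short-gap interpolation, hourly
    aggregation), a registry of contiguous missing runs, a hierarchy of
    imputers from statistical baselines through bidirectional
    sequence-to-sequence regressors with distance-weighted fusion, a dynamic
    adaptive-context imputer that handles gaps of arbitrary length with a
    single model, a synthetic-gap benchmarking harness with standardized
    error metrics, and downstream WHO-guideline exceedance and air-quality
    index assessment of the filled series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    RSQLite,
    DBI
Config/testthat/edition: 3
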