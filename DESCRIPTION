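Package: gwindex
Title: Groundwater Quality Indices, Intervention Statistics and Interpolated Surfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the weighted-arithmetic water quality index (WQI) and
    the contamination degree index (Cd) for groundwater monitoring wells,
    classifies samples into five quality ranks, compares pre- and
    post-sewerage periods with Wilcoxon signed-rank tests, Spearman rank
    correlation and Fisher two-group discriminant analysis (Wilks' Lambda,
    leave-one-out cross-validation), and interpolates classified
    water-quality surfaces by ordinary kriging with an inverse-distance
    fallback. Includes a calibrated synthetic monitoring-network simulator
    so the whole pipeline is testable without access to raw well
    measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
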