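Package: stridevar
Title: Stride-Count Requirements for Reliable Gait Variability Measurement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how many strides are needed to measure gait
    variability reliably from ambulatory sensor exports. Simulates cohorts of
    stride-wise gait recordings with 180-degree turns, peri-turn stride
    perturbations and injectable missed-turn artifacts; detects turns as
    timestamp gaps and quality-controls trials for non-detected turns;
    excises turns (standard and generous modes); computes coefficients of
    variation of stride length and stride time per walking segment and
    cumulatively; and estimates the minimum stride count for a reliable
    variability estimate via segment-wise ICC(2,1) and the correlation of
    cumulative statistics with their final-stride value.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    graphics,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
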