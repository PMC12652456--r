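Package: tanninfuse
Title: Dual-Sensor Hyperspectral Fusion for Sorghum Tannin Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A chemometrics workflow for non-destructive prediction of
    sorghum grain tannin content from dual hyperspectral sensors (VNIR,
    430-900 nm; SWIR, 950-1650 nm). Implements competitive adaptive
    reweighted sampling (CARS) wavelength selection, data-level and
    feature-level sensor fusion, partial least squares, RBF support
    vector regression and 1-D convolutional network calibration models,
    and the standard calibration diagnostics (R2, RMSE, RPD, bias, SEP,
    confidence intervals, ANOVA with Tukey HSD model comparison). A
    seeded synthetic dual-sensor spectra generator emulating the study
    design makes the whole pipeline testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    mixOmics,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
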