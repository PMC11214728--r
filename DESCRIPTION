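Package: memlong
Title: Measurement-Error Correction for Longitudinal Exposure-History Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Corrects bias from mismeasured exposure histories in longitudinal
    studies with continuous outcomes under a main-study/validation-study
    design. A calibration-type measurement error model fitted in the
    validation study (least squares or generalized estimating equations) is
    combined with an outcome-model GEE through stacked estimating equations;
    the sandwich variance propagates the validation-stage uncertainty into
    inference on the exposure-by-time coefficient. Supports cumulative
    average, moving average and cumulative sum exposure-history functionals,
    internal and external validation designs, diagnostics for the localized
    error and surrogacy assumptions, and a Monte-Carlo simulator for
    factorial measurement-error scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
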