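Package: ampmyield
Title: Daily Milk Yield Estimation from AM-PM Milking Plans
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimators of daily milk yield (DMY) from a single morning (AM)
    or evening (PM) milking under AM-PM milk-recording plans: doubling,
    additive correction factors (ACF) with categorical or continuous milking
    interval, free-coefficient linear regression, ratio-based multiplicative
    correction factors (MCF) in the Shook-Jensen-Dickinson, DeLorenzo-Wiggans
    and Wiggans traditions, and an exponential regression model with a
    lognormal-moment correction. Includes milking-interval-class
    discretization, factor-table construction, replicated k-fold
    cross-validation with variance/squared-bias decomposition of the mean
    squared error, R-squared accuracy, cubic-smoothing-spline
    characterization of yields and accuracies, and a calibrated synthetic
    generator of paired AM/PM test-day records for method evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    readr,
    rlang,
    withr,
    yaml,
    mgcv
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
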