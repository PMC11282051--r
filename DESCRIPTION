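Package: calentropy
Title: Cross-Sectional Average Length of Life Entropy and Its Decompositions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring relative lifespan inequality from age-by-year
    mortality surfaces. Implements the Keyfitz-Leser life table entropy for
    period and cohort life tables, the cross-sectional average length of life
    (CAL) together with its lifespan-variation analogue (CAL-dagger) and their
    ratio, the CAL-entropy; a decomposition of cross-population CAL-entropy
    gaps into lifespan-variation and longevity contributions; and a
    differences-of-differences decomposition of the change in those gaps over
    time. Includes readers for Human Mortality Database style rate files, a
    configurable Gompertz-Makeham mortality-surface simulator for fully
    synthetic analyses, trend summaries (linear and two-segment piecewise
    fits, intrinsic rates of change), and ggplot2 visualisations.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
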