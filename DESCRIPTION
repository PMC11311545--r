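Package: idmsquant
Title: Isotope Dilution Mass Spectrometry Quantification with GUM and
    Monte Carlo Uncertainty Budgets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification of trace analytes (melamine and cyanuric acid in
    infant formula and similar matrices) by exact-matching double isotope
    dilution mass spectrometry (EMD-IDMS) and matched standard-addition IDMS
    (MSA-IDMS) from gravimetric blend tables and measured isotopologue signal
    ratios. Provides the ratio-of-ratios and linearized standard-addition
    estimators, first-order GUM uncertainty budgets with finite-difference
    sensitivity coefficients and contribution indices, Monte Carlo coverage
    intervals with nested regression re-fitting, matching and linearity
    quality checks, bias and repeatability statistics, and a synthetic
    experiment generator for robustness and coverage studies. Blend tables
    read and write a plain CSV dialect; results serialize to JSON reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
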