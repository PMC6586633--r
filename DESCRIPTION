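Package: prmquant
Title: High-Resolution Parallel Reaction Monitoring Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for absolute protein quantification by high-resolution
    parallel reaction monitoring (PRM) with stable-isotope-labeled internal
    standards. Covers extracted-ion-chromatogram peak detection and
    integration with spectral dot-product quality control, weighted
    calibration curves with limit-of-quantification determination by the
    back-calculated-deviation rule, isotope-dilution absolute amounts and
    copy-number-per-cell estimates, scheduled-acquisition method design with
    a cycle-time model, and a seeded orbitrap-PRM acquisition simulator that
    reproduces the resolution, injection-time and isolation-width trade-offs
    of the instrument, so that every stage of the workflow can be exercised
    and validated without raw instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    stringr,
    ggplot2,
    generics,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    mzR,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
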