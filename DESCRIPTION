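Package: peakfill
Title: Baseline Estimation for One-Dimensional Spectra by Iterative Mean Suppression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates and subtracts slowly varying baselines from one-dimensional
    spectra (MALDI-TOF mass spectra, LIBS emission spectra, Raman, and similar)
    using the 4S peak-filling procedure: Whittaker smoothing with a second-derivative
    penalty, subsampling by bin minima, iterative bidirectional moving-window
    suppression with a logarithmically shrinking window, and stretching back to full
    resolution by linear or shape-preserving spline interpolation. Includes a
    synthetic-spectrum generator with known ground-truth baselines for validation,
    broom-style tidiers for fitted baselines, ggplot2 autoplot methods, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    data.table,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
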