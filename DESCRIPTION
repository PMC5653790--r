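Package: ringclock
Title: Circadian Analysis of Concentric Growth Rings in Fungal Colonies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to detect and quantify circadian rhythms in the concentric
    ring patterns of fungal colonies grown on solid media. Provides a
    synthetic colony-image generator with known clock parameters, an image
    pipeline (region-of-interest extraction, Gaussian smoothing, pseudo
    flat-field illumination correction, radial profile collapse), rhythm
    analysis (ring detection, pixel-to-hour calibration, quadratic
    detrending, zero-padded DFT periodogram, free-running period
    estimation), double-plotted actograms with jet-lag phase-shift
    estimation, and temperature-compensation summaries (Q10, one-way ANOVA
    across temperatures). Results are tibbles or small result objects with
    tidy() and glance() methods and ggplot2 autoplot() methods.
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
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
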