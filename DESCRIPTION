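Package: icgquant
Title: Objective Quantification of Indocyanine Green Fluorescence in Surgical RGB Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies indocyanine green (ICG) fluorescence intensity in
    still RGB images from fluorescence-mode laparoscopy. Pixels whose
    predominant colour is not green (specular reflections, white light) are
    discarded by a strict green-dominance filter; intensity statistics are
    computed over user- or automatically-placed rectangular regions of
    interest on the 0-255 green-channel scale. Segment-level means feed the
    perfusion metrics AMISD (absolute mean ICG saturation decrease) and
    RMISD (relative decrease, percent), with a configurable ischemia
    threshold, plus the accompanying study-level statistical toolkit
    (t-based confidence intervals, pooled two-sample t-tests, one-way
    ANOVA, Kolmogorov-Smirnov normality screening). Ships a built-in
    porcine colon study matrix as a verified fixture and synthetic
    generators for images and study matrices with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    png,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    grDevices,
    yaml
Suggests:
    jpeg,
    nortest,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
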