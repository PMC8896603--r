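Package: slidenorm
Title: Slide-to-Slide Normalization and Evaluation for Multiplexed Immunofluorescence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Normalizes segmented single-cell marker intensities from multiplexed
    immunofluorescence imaging to remove slide-level batch effects. Implements three
    intensity-scale transformations (log10, mean division, mean division log10)
    crossed with two normalization algorithms: an empirical-Bayes location-scale
    (ComBat-style) slide correction and a functional-data density-registration method
    that warps per-slide intensity distributions onto their cross-slide average.
    Includes a quantitative evaluation framework (k-sample Anderson-Darling density
    alignment, Otsu threshold discordance and marker-positive accuracy,
    random-intercept slide variance proportions, UMAP/k-means adjusted Rand indices)
    and a synthetic-data generator with known slide effects for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    lme4,
    optparse,
    purrr,
    readr,
    rlang,
    splines,
    stats,
    tibble,
    tidyr,
    utils,
    uwot,
    withr,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
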