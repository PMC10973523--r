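Package: pdl1quant
Title: Digital PD-L1 Scoring for Diffuse Large B Cell Lymphoma IHC Slides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An image-analysis pipeline for quantifying PD-L1 expression on
    DAB/hematoxylin immunohistochemistry slides of diffuse large B cell
    lymphoma (DLBCL). Provides region-of-interest delineation by tile
    classification and annotation inversion, cell center detection on the
    hematoxylin optical-density channel, point-to-mask nucleus segmentation
    with boundary dilation, stain separation by Beer-Lambert color
    deconvolution, per-cell positivity by the brown-area ratio, and an
    area-ranked tumor-cell selection rule yielding a modified tumor
    proportion score (TPS*) alongside the traditional TPS. Includes inter-
    rater concordance statistics (two-way mixed average-measures intraclass
    correlation, stratified agreement, log-scale MSE), a synthetic IHC
    generator with per-cell ground truth for end-to-end validation, readers
    and writers for ASAP polygon annotations and LabelMe point annotations,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tiff,
    knitr
Config/testthat/edition: 3
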