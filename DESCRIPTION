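Package: fruitpix
Title: Batch Image-Based Fruit Phenotyping by Color Thresholding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Batch pipeline for measuring fruit size and color-defined
    surface features (such as red drupelet reversion in blackberry) from
    staged photographs. Detects fruit on a uniform contrasting background
    by conjunctive colorspace thresholds in RGB, HSB and CIELAB, removes
    small debris by morphological despeckling, labels individual fruit as
    8-connected components, converts pixel measurements to millimetres
    via a size reference of known length, and quantifies colored features
    as pixel fractions of fruit area. Includes a synthetic scene
    generator with exact ground truth for validation, a YAML
    configuration layer that records all settings for repeatability, and
    a command-line interface for batch analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
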