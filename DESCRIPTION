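Package: sourflow
Title: Non-Invasive Specific Oxygen Uptake Rates in Perfused Microfluidic Cell Culture
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quantifies specific oxygen uptake rates (sOUR) of adherent cell
    cultures in a perfused microfluidic chamber, non-invasively and in real
    time. Cell density is estimated from phase-contrast microscopy tiles via
    trainable pixel segmentation, confluency, and a packing-corrected
    confluency conversion; oxygen uptake is obtained from the inlet-outlet
    dissolved-oxygen differential of optical sensors calibrated with a
    two-point Stern-Volmer relation. Includes growth-kinetics extraction
    (growth rate, doubling time, lag), respiratory event detection from the
    in-situ sensor, and a ground-truthed synthetic-data generator (phase
    contrast-like images and sensor traces) for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tiff,
    yaml,
    jsonlite,
    glmnet,
    EBImage,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
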