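Package: plumfuse
Title: Multi-Source Fusion of Vis/NIR Spectra and Fruit Images for Soluble
    Solids Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A chemometrics pipeline for predicting the soluble solid content
    (SSC, degrees Brix) of plums from visible/near-infrared reflectance spectra
    (400-1100 nm) fused with color and texture features of RGB fruit images.
    Implements reflectance calibration against dark-current and white-reference
    spectra; Savitzky-Golay, standard normal variate and multiplicative scatter
    correction preprocessing and their combinations; three wavelength-selection
    algorithms (competitive adaptive reweighted sampling, the successive
    projections algorithm, and uninformative variable elimination); a
    16-dimensional visual feature vector (RGB and CIELAB channel statistics plus
    four gray-level co-occurrence matrix textures); Z-score standardization with
    ordinary-least-squares-learned linear fusion weights; and partial least
    squares regression with cross-validated latent-variable selection. A seeded
    synthetic-data generator emulates the statistical structure of free-fall
    plum acquisitions so the full pipeline is testable without instrument data.
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
    grDevices,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
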