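Package: mirwalnut
Title: Mid-Infrared Spectral Authentication of Walnut Origin and Variety
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A chemometrics pipeline for authenticating the geographic origin
    and variety of walnut (and similar food products) from Fourier-transform
    mid-infrared absorbance spectra. Provides wavelet denoising of spectra,
    wavelength selection by uninformative variable elimination chained with the
    successive projections algorithm (UVE-SPA) and by genetic-algorithm partial
    least squares (GA-PLS), a NIPALS PLS engine with cross-validation, five
    classifiers (extreme learning machine, random forest, radial basis function
    network, PLS-DA, back-propagation neural network) behind one fit/predict
    contract, principal component exploration, task runners for origin and
    variety classification designs, and a seeded synthetic FT-MIR spectrum
    generator with known informative bands for end-to-end testing.
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
    jsonlite,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    mixOmics,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
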