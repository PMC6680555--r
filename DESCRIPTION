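Package: irfuse
Title: Two-Block Infrared Spectral Data Fusion for Origin Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Chemometric pipeline for classifying the geographic origin of
    plant material from paired Fourier-transform mid-infrared (FT-MIR) and
    near-infrared (NIR) absorbance spectra. Implements spectral pretreatment
    (standard normal variate, Savitzky-Golay derivatives), per-class
    Kennard-Stone calibration/validation splitting, PLS-DA with VIP scores
    and permutation testing, out-of-bag-tuned random forests, three variable
    selection routes (Kaiser-rule PCA, recursive feature elimination,
    Boruta), and low-, mid-, and high-level data fusion of the two spectral
    blocks, the last via fuzzy-aggregation decision voting. Ships a
    synthetic two-block spectra generator so the full pipeline is testable
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    randomForest,
    ranger,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mixOmics
Config/testthat/edition: 3
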