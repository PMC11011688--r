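Package: beefhsi
Title: Hyperspectral Imaging Chemometrics for Fresh, Frozen-Stored and
    Frozen-Thawed Beef
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A chemometrics pipeline for discriminating fresh, frozen-stored
    and repeatedly frozen-thawed beef cuts from visible/near-infrared
    hyperspectral reflectance cubes (400-800 nm, 251 bands). Provides
    black/white reference calibration, nearest-standard-spectrum tissue
    segmentation into muscle and fat, spectral preprocessing
    (Savitzky-Golay smoothing, first derivative, standard normal variate,
    detrending), competitive adaptive reweighted sampling (CARS) wavelength
    selection with an internal cross-validated partial least squares
    engine, three classifiers (PLS-DA with ordinal class coding, one-vs-rest
    radial-basis SVM, a back-propagation neural network), SPXY sample-set
    partitioning, stratified cross-validation, confusion-matrix metrics,
    spectral angle mapper summaries, and pixel-wise deterioration-index
    maps. A synthetic beef-scene generator reproduces the spectral
    phenomenology the method assumes (pigment and oxidation absorption
    bands, fat/muscle contrast, freshness-ordered reflectance decline,
    marbling geometry, scatter, drift and noise) so the whole pipeline is
    testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    grDevices,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    signal,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
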