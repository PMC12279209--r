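Package: cardiopatch
Title: Left-Ventricle Infarct Mechanics with Epicardial Patches and
    Promoter-Accessibility Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Passive end-diastolic mechanics of the infarcted left ventricle
    by finite-strain finite elements: idealized truncated-ellipsoid ventricular
    meshes with rule-based myofiber architecture, Holzapfel-Gasser-Ogden
    myocardium with an isotropic infarct and a bonded epicardial patch, follower
    endocardial pressure and Newton iteration with consistent tangents.
    Companion analyses: marker-grid strain estimation for ex vivo stretch tests,
    stress/von Mises/principal-stress endpoints, patch modulus-thickness sweeps,
    a promoter-window chromatin-accessibility ratio screen, and a Recovery
    Percentage outcome metric. Synthetic-data generators provide ventricle
    presets, noisy marker grids and overdispersed peak-count tables with known
    ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    yaml,
    xml2,
    jsonlite,
    IRanges,
    GenomicRanges,
    S4Vectors
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
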