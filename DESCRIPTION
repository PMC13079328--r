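Package: pvstopo
Title: Spatial Coupling of Enlarged Perivascular Spaces and White Matter
    Lesions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the spatial topology of enlarged perivascular
    spaces (EPVS) relative to white matter lesions (WML) from 3D
    segmentation masks. Provides connected-component morphometry,
    cross-kernel boundary shells, exact nearest-boundary Euclidean
    distances via an expanding-window search, penumbra proximity
    categories and 5 mm distance bins, regional burden metrics with
    intracranial-volume normalization, negative-binomial and
    zero-inflated count models with FDR control, segmentation-agreement
    metrics, and a synthetic cohort generator with known group effects
    and distance-decay coupling for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    MASS,
    RNifti,
    Rcpp,
    glmmTMB,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    lmtest,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
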