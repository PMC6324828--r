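Package: stackmorph
Title: Joint Restacking and Diffeomorphic Atlas Mapping for Serial-Section Histology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs three-dimensional volumes from serially sectioned
    histology by jointly estimating per-section in-plane rigid motions and a
    diffeomorphic mapping of a reference atlas onto the restacked volume. The
    rigid restacking is regularized by a first-order Sobolev smoothness prior
    along the cutting axis and Gaussian priors on the section motions; the
    atlas mapping uses large deformation diffeomorphic metric mapping (LDDMM)
    with an FFT-realized Green's kernel and Beg-style gradient descent.
    Includes phantom simulators for curved, cylindrical and brain-like test
    objects, a sectioning/jitter/noise observation model, and a replicate
    harness for bias, variance and RMSE statistics of the rigid-motion
    estimators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    RNifti,
    png,
    tiff,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    oro.nifti,
    optparse,
    yaml
Config/testthat/edition: 3
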