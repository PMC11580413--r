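Package: softAFM
Title: Simulation of Atomic Force Microscopy Imaging on Deformable Samples
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulates atomic force microscopy (AFM) imaging of soft,
    elastically deformable samples. A rigid cone-plus-spherical-cap tip is
    scanned over parametric sample geometries (spheres, hemispheres,
    sinusoidal surfaces) or molecular surfaces built from atomic van der
    Waals radii. Tip-sample forces are computed as a function of
    three-dimensional tip position, either from closed-form contact
    mechanics (Hertz, conical Sneddon, double-contact series compliance)
    or from a boundary-element elastic half-space contact solver, and AFM
    images are extracted as contours of equal vertical force. Analysis
    utilities quantify apparent feature width (FWHM), apparent volume,
    Fourier content of periodic topographies, and apparent Young's moduli
    from force-curve fits.
License: MIT
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    bio3d,
    pracma,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
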