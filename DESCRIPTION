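Package: tigrade
Title: Functional Grading of Transversely Isotropic Hyperelastic Soft Tissue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for modeling transition regions between fiber-reinforced
    soft tissues (e.g. the chordae tendineae, leaflet and papillary muscle of
    porcine heart valves) with a functionally graded transversely isotropic
    (TI) hyperelastic material. Implements the Weiss-type TI constitutive law
    with an exponential toe region and linear fiber-extension regime, a
    grading-stiffness metric, an interpolation law that grades the TI
    parameters across discrete transition layers under a constituent
    distribution function, several sigmoidal distribution-function families
    with smoothness-constrained asymmetric variants, a one-dimensional graded
    serial-chain tension simulator, and inverse estimation of both terminal
    TI parameters from force-displacement curves and distribution shape
    parameters from normalized fiducial strain profiles. Seeded synthetic
    data generators emulate the X-ray-diffraction-derived inputs used to
    inform and validate such models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    lhs,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
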