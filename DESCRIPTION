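Package: motinv
Title: Motion Invariants of Images and Volumes from Correlation Functions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rotation-and-translation ("motion") invariant descriptors of 2D
    images and 3D volumes built from two-, three- and four-point correlation
    functions. Implements the radial power spectrum (RPS) and radial
    distribution function (RDF) with the Bessel-kernel transforms that relate
    them in dimensions 2, 3 and 4; the rotationally averaged bispectrum
    (RABS) of 2D signals in both Fourier and real space together with the
    kernel that maps one to the other; closed-form invariants for
    Gaussian-mixture (Wilson model) signals, including a symmetric triangle
    coordinate system (drop, short side, signed angle) in which mirroring is
    a sign flip of the angle; and a four-point helical probe that detects the
    chirality and pitch of point helices buried in noisy volumes. Synthetic
    pattern generators (Gaussian mixtures, Bessel ring and angular-harmonic
    patterns, noisy propeller volumes) and a small command-line interface are
    included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
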