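Package: maxgirf
Title: Higher-Order Image Reconstruction for Non-Cartesian MRI with
    Concomitant-Field and Gradient Impulse Response Correction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a higher-order encoding model for spiral
    (non-Cartesian) MRI, known in the field as MaxGIRF. Nominal gradient
    waveforms are corrected by per-axis gradient impulse response functions
    (GIRFs); the predicted gradients drive an analytic concomitant (Maxwell)
    field model which, together with a static off-resonance map, forms a
    per-interleaf higher-order encoding matrix. Images are reconstructed by
    conjugate-phase or iterative least-squares (LSQR) solvers using either
    dense operators or a low-rank singular value decomposition of the
    higher-order phase term. Includes a multi-echo off-resonance map
    estimator (iteratively regularized Gauss-Newton with a Sobolev-norm
    preconditioner), a slew- and amplitude-constrained spiral designer, and a
    synthetic acquisition simulator so the entire pipeline is testable
    without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    pracma,
    stats,
    graphics,
    grDevices,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
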