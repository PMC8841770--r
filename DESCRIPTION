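Package: eitclean
Title: Wavelet-Based Motion-Artifact Removal for Thoracic Electrical
    Impedance Tomography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and removes the three common classes of motion artifact in
    multichannel thoracic electrical impedance tomography (EIT) recordings --
    baseline drifting, step-like baseline shifts, and spike-like transients --
    using a multilevel discrete wavelet transform (Daubechies db8 filter bank)
    with coefficient masking. Includes a synthetic generator for the
    two-sinusoid breathing-plus-cardiac signal with configurable artifact
    injection, a linear difference-imaging stage (finite-element forward model
    and one-step Tikhonov inverse on a 16-electrode unit-disk phantom), and the
    signal- and image-level quality metrics (percent root difference,
    variance-ratio R-squared, image error, image correlation) used to quantify
    artifact removal.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
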