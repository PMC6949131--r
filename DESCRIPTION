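Package: psoct
Title: Polarization-Sensitive Spectral-Domain OCT Reconstruction and
    Corneal Texture Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Post-processing chain for ultrahigh-resolution
    polarization-sensitive spectral-domain optical coherence tomography
    (PS-OCT) of the cornea: dual-spectrometer k-space calibration,
    DC/fixed-pattern removal by mean-spectrum subtraction, scan-position
    dependent (variable) numerical dispersion compensation, two-channel
    tomogram reconstruction, surface detection and flattening, and the
    integrated autocorrelation factor (IACF) statistic that quantifies
    depth-varying stromal texture in cross-polarized en-face images.
    Includes a synthetic raw-fringe simulator of a layered corneal
    phantom under conical scanning, with known ground-truth dispersion,
    surface position, axial motion and texture statistics, so that every
    stage of the chain can be validated against an oracle at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    tiff
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
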