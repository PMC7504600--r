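Package: helixdti
Title: Transmural Helix- and Sheet-Angle Analysis for Ex Vivo Cardiac
    Diffusion Tensor Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for microstructural analysis of ex vivo cardiac
    diffusion tensor imaging (DTI) in congenital heart disease. Provides
    a synthetic myocardial phantom and diffusion-weighted signal
    simulator (half-shell gradient schemes, Rician noise, signal
    averaging), log-linear least-squares tensor fitting with mean
    diffusivity and fractional anisotropy maps, transmural depth and
    local radial/circumferential/longitudinal frame construction from
    myocardial label maps, per-voxel helix-angle (HA) and sheet-angle
    (E2A) maps, per-segment transmural HA profiles, and statistics for
    the transmural HA gradient and HA asymmetry (zero-crossing depth
    with confidence intervals from the regression confidence band),
    including between-group slope and E2A comparisons and cohort
    summaries.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    RNifti,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
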