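Package: aortaflow
Title: Hemodynamic Analysis of 4D Phase-Contrast MRI of the Thoracic Aorta
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies thoracic-aorta hemodynamics from time-resolved
    three-directional phase-contrast MRI (4D flow MRI) velocity fields and
    labelled segmentation masks: flow-rate curves and cardiac metrics (net
    volume, regurgitant fraction, cardiac output, kinetic energy), arterial
    stiffness (transit-time pulse wave velocity, Bramwell-Hill
    distensibility, area pulsation, pressure drop), short-axis plane
    analysis (axial vorticity, wall-to-wall chord profiles, axial and
    tangential wall shear stress, oscillatory shear index) and
    segmentation evaluation (Dice score, cross-sectional areas). Includes
    a synthetic curved-tube aorta flow phantom with tricuspid (TAV) and
    bicuspid (BAV) aortic-valve flow patterns so the full pipeline is
    testable without patient data, and NIfTI input/output with acquisition
    metadata sidecars.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    RNifti,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
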