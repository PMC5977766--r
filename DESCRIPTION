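Package: ffrsens
Title: Sensitivity of Fractional Flow Reserve to Stenosis Geometry
    Reconstruction Errors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to study how lumen-geometry reconstruction errors and
    modelling approximations propagate into the fractional flow reserve
    (FFR) of an idealized highly-eccentric coronary stenosis. Provides a
    parametric cylinder-minus-sphere stenosis model with severity
    calibration and segmentation-error perturbation, faceted (STL)
    surface generation with a surface resolution index, Womersley inlet
    velocity profiles and Carreau shear-thinning rheology, a calibratable
    reduced-order pressure-drop surrogate, the clinical moving-window FFR
    statistic with first-order error propagation, FFR-versus-severity
    sweep drivers with histogram-level clinical-impact remapping, and
    seeded generators for synthetic coronary pressure and velocity
    waveforms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
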