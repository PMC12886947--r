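Package: laflow
Title: Hemodynamic Analysis of 4D Flow MRI in the Left Atrium
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying left-atrial hemodynamics from time-resolved
    three-directional phase-contrast MRI (4D flow MRI). Computes time-averaged
    phase-contrast MR angiograms (PC-MRA), kinetic energy, viscous energy loss,
    vorticity and Q-criterion vortex-core metrics over a segmented left atrium,
    sphere-seeded pulmonary-vein and mitral flow-rate waveforms with S/D/Ar and
    E/A feature extraction, indexed left-atrial volumetrics with biplane
    comparison and Bland-Altman agreement, segmentation-overlap metrics (Dice,
    HD95), particle pathline tracing, age-adjusted cohort statistics (ANCOVA,
    Tukey, Benjamini-Hochberg, Cohen's d), and deterministic analytic flow
    phantoms for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    RNifti,
    Matrix,
    xml2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    multcomp,
    car,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
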