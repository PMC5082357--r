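Package: ewavekit
Title: Kinematic Analysis of Transmitral Doppler E-Waves
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies early diastolic left-ventricular filling from
    pulsed-wave Doppler echocardiograms using the kinematic (parameterized
    diastolic filling) model, in which each E-wave is the recoil of a damped
    loaded spring with stiffness k, viscoelastic damping c and load x0.
    Provides spectral-envelope detection from calibrated Doppler pixel
    strips, Levenberg-Marquardt estimation of the model constants, the
    triad (acceleration time, deceleration time, peak velocity)
    parameterization and its closed-form inversion, derived physiological
    indices (VTI, KFEI, peak driving and resistive forces, filling energy,
    damping index, tau), semi-automatic multi-beat fitting with template
    matching, the load-independent index M, DICOM ultrasound-region input
    and output, session persistence, spreadsheet export, reproducibility
    statistics (CV, ICC, percentage difference), and a seeded synthetic
    Doppler generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    minpack.lm,
    jsonlite,
    withr,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
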