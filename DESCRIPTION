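Package: centralbp
Title: Subject-Specific Multiscale Modelling of Central Aortic Pressure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Noninvasive appraisal of central (aortic) systolic and diastolic
    blood pressure with a multiscale cardiovascular model: one-dimensional
    pulse-wave propagation in a distributed large-artery network with
    viscoelastic walls, coupled to a lumped time-varying-elastance left
    ventricle with pressure-gated valves and three-element Windkessel
    microcirculation loads. An automatic subject-specific setting procedure
    tailors the model to an individual from routine measurements (brachial
    pressure, anthropometry, heart rate, ventricular volumes and regional
    pulse wave velocities). Includes foot-to-foot pulse-wave-velocity waveform
    analysis, a method-comparison statistics pipeline (paired tests,
    regression, Bland-Altman limits of agreement, accuracy classification,
    regressor selection and commonality analysis), and a seeded synthetic
    cohort generator with a statistical emulator of a tonometric reference
    device, so that the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
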