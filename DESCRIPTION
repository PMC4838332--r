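Package: batmoth
Title: Bat-Moth Acoustic Interaction Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing field-recorded interactions between
    echolocating bats and sound-producing tiger moths. Provides
    inter-pulse-interval attack-phase classification of bat call
    sequences, critical-window sonar-jamming assessment of moth click
    trains, smoothing-spline 3-D flight-path kinematics (minimum
    bat-moth distance, pre-encounter z-speed, evasion classification),
    exact statistics over interaction outcomes (Fisher conditional-MLE
    odds ratios, exact binomial palatability bounds, relative risk),
    and a seeded synthetic interaction generator that emulates the
    structure of such field data for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    car
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'acoustics.R'
    'kinematics.R'
    'jamming.R'
    'stats.R'
    'synthetic.R'
    'io.R'
    'pipeline.R'
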