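Package: stereobat
Title: Stereo Thermal Videogrammetry and Deterrent-Response Analysis for
    Free-Flying Bats
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to reconstruct three-dimensional bat flight trajectories
    from synchronized two-camera thermal video and to analyse the behavioural
    response of bats to ultrasonic acoustic deterrents. Implements pinhole
    stereo camera calibration from a thermal bulb target, background
    subtraction and blob detection, cross-camera pairing and trajectory
    linking with quality control, per-trajectory flight metrics (speed,
    tortuosity, distance, height), an ISO 9613-1 atmospheric absorption
    sound-field model for the deterrent speakers, block-design aggregation of
    acoustic pass counts, and the mixed-model statistics (Poisson/negative
    binomial GLMMs, Gaussian LMMs, beta GLMMs, AICc model selection,
    likelihood ratio tests) used to quantify deterrent effects. A synthetic
    scene generator produces ground-truth flights, rendered frame stacks,
    calibration sequences, count tables and echolocation call parameters so
    the whole pipeline is testable without field recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    lme4,
    glmmTMB,
    MASS,
    tiff,
    yaml,
    EBImage,
    withr,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
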