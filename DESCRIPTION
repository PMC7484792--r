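Package: footpower
Title: Six Degrees-of-Freedom Ankle and Distal Foot Power Analysis for Gait
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes mechanical power of the ankle-foot system during the
    stance phase of walking from 3D marker trajectories and force-plate
    signals. Implements a six degrees-of-freedom ankle joint power (force
    times translational velocity plus moment times angular velocity across
    the joint) together with the distal power of a rigid foot segment loaded
    through the centre of pressure and the free moment. Provides zero-lag
    Butterworth filtering, force-threshold gait event detection, Newton-Euler
    inverse dynamics of the foot, extraction of peak power and positive and
    negative work features, and a standardized linear mixed-effects model
    ladder to quantify walking speed and age-group effects on those features.
    A synthetic-trial generator with analytic, dynamically consistent ground
    truth and an energy-balance oracle makes every pipeline stage testable
    without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    lme4,
    signal,
    yaml,
    jsonlite,
    pracma,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
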