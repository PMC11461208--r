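Package: tapfatigue
Title: Quantifying Motor Fatigability from Smartphone Finger-Tapping Sessions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for quantifying motor slowing (motor fatigability) from
    30-second maximal-speed finger-tapping trials recorded on a touchscreen
    device. Parses raw 50 Hz touch and accelerometer streams, assigns touch
    tracks to anatomical fingers, applies a seven-criterion trial quality
    check with a trial-to-finger-to-participant exclusion cascade, computes
    binned tapping-speed curves and relative/absolute decrease features, and
    fits linear mixed-effects models with type-III F tests, partial eta
    squared effect sizes, and family-wise-error-corrected post-hoc
    contrasts. A synthetic session generator with controllable quality
    violations supports end-to-end testing and power studies without access
    to raw participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    lme4,
    lmerTest,
    emmeans,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
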