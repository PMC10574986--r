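Package: kneesim
Title: Virtual Knee-Joint Simulator for Post-Arthroplasty Ligament and
    Implant-Alignment Sensitivity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A rigid-body simulator of a posterior-stabilized total knee
    arthroplasty knee performing a hip-displacement-driven squat on a
    virtual joint rig.  Ligaments follow the Blankevoort piecewise
    tension-strain law, articular interfaces use a compliant
    penetration-depth contact model, and the quadriceps actuator is
    regulated by a PID controller that maintains a constant vertical
    ankle load.  Tibiofemoral kinematics are expressed in the
    Grood-Suntay joint coordinate system.  The package generates seeded
    synthetic post-TKA knee geometry, calibrates ligament stiffness
    against reference traces, and runs a two-arm sensitivity study
    comparing ligament-stiffness perturbations matched to
    ultrasound-based strain residual errors with implant
    internal-external malrotation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
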