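Package: hemoloop
Title: Hybrid Closed-Loop Cardiovascular Simulator with a Virtual Soft Robotic Left Ventricle
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A lumped-parameter (0D) closed-loop cardiovascular simulator based
    on time-varying elastance heart chambers, diode valves and three-element
    Windkessel systemic and pulmonary beds, advanced at a fixed 1-ms step to
    mirror real-time hardware-in-the-loop operation. A virtual soft robotic
    left-ventricle phantom (passive compliant chamber, static pressure-volume
    characterization, and a two-pump activation controller) can replace the
    in-silico left ventricle at every time step. Includes patient-specific
    personalization from routine hemodynamic records (systemic and pulmonary
    vascular resistances, ventricular elastance fitting, automated compliance
    tuning), beat-averaged summary statistics, and a verification harness
    comparing simulated to clinical hemodynamics with nominal percentage
    errors. Ships reference records for three patient profiles: heart failure
    with preserved ejection fraction, healthy, and dilated cardiomyopathy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
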