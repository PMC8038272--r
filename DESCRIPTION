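Package: ergorula
Title: Wearable IMU Posture Monitoring and RULA-Derived Ergonomic Risk Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processes orientation streams from three body-worn inertial
    measurement units (sacral, thoracic, head) into calibrated spine and neck
    joint angles (flexion-extension, lateral bending, axial twist) and a
    time-varying ergonomic risk index for the head-and-trunk region derived
    from the RULA section-B scoring scheme: moving-average smoothing,
    5-minute tumbling windows, staircase angle quantization, dwell-time score
    selection, twist/bend adjustments and look-up-table combination. Includes
    a synthetic scenario generator with ground-truth scores so the whole
    pipeline is testable without hardware, plus command-line entry points for
    simulation, scoring and reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
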