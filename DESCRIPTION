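Package: spastiglove
Title: Sensor-Glove Kinematics and Nonparametric Screening for Finger Spasticity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis pipeline for a 19-IMU sensor glove with a
    pressure-ball module used to assess finger spasticity after stroke. Provides
    a synthetic session generator (periodic flexion cycles, spasticity-dependent
    kinematics, magnetometer hard/soft-iron distortion, squeeze-pulse pressure
    traces), min/max magnetometer calibration, pressure-ball offset calibration,
    complementary-filter attitude and joint-angle estimation, extraction of 20
    time- and frequency-domain statistics per signal-magnitude channel (1140
    features per session, 1160 with the pressure ball), and exact nonparametric
    screening (rank-sum and Kruskal-Wallis) that separates healthy subjects from
    stroke patients with finger spasticity and grades spasticity levels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
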