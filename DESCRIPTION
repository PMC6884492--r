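Package: remotegait
Title: Remote Free-Living Gait Analysis from Bilateral Thigh Accelerometry and Surface EMG
Version: 0.1.0
Authors@R:
    person("Remotegait", "Developers", email = "remotegait@example.org", role = c("aut", "cre"))
Description: Analytical pipeline for remote gait analysis from a single
    wearable sensor per thigh recording tri-axial acceleration (31.25 Hz)
    and surface electromyography (250 Hz). Identifies walking bouts with a
    Gaussian-kernel support vector machine over Davies-Bouldin-selected
    window features, segments strides and gait phases from the
    cranial-caudal acceleration using a lowpass filter bank and Welch
    power-spectral-density cadence estimates, and computes seven inter-limb
    asymmetry indices (duty factor, stance/swing muscle activation, and
    waveform pattern asymmetries of the sEMG envelope and the three thigh
    acceleration axes) plus their composite score for tracking
    rehabilitation after anterior cruciate ligament reconstruction. Includes
    a fully seeded synthetic gait and activity simulator with ground-truth
    events so every stage is testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
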