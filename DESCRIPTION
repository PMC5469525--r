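Package: gaitscore
Title: Acceleration-Based Gait Assessment from Wearable IMU Sensors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative gait-abnormality scoring from tri-axial inertial
    measurement units worn at the waist and both thighs. Raw accelerometer
    and gyroscope streams are calibrated, rotated into an anatomical
    anterior-posterior / superior-inferior / medio-lateral frame via
    quaternion integration, and low-pass filtered. Gait cycles are cut at
    heel-strike peaks of the waist anterior-posterior acceleration,
    time-normalized, and averaged into per-subject gait graphs. Five
    waveform features (Pearson similarity to a healthy reference, variance
    ratio, extreme-point count, harmonic ratio, and step-symmetry
    autocorrelation) feed a grey relational analysis model that scores gait
    on a 0-100 scale. A parameterized synthetic gait generator with known
    heel-strike ground truth and adjustable asymmetry, tremor, and
    cycle-to-cycle variability supports validation without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
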