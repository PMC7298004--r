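Package: hivewatch
Title: Swarm Prediction and Queen-Pipe Detection from Hive Vibration Spectra
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for predicting honeybee (Apis mellifera) swarming from
    continuous in-hive accelerometer monitoring.  Time series of 3-minute
    averaged vibration power spectra are classified with a trained
    discriminant model (principal component reduction followed by
    discriminant function analysis), either from instantaneous night-time
    spectra or from multi-day spectral-evolution features built with two-
    and three-dimensional Fourier transforms.  The package also generates
    labelled synthetic hive-vibration data with known ground truth,
    converts model output into hourly and nightly swarm alarms with lead
    times and cohort performance summaries, and detects queen piping
    signals (toots and quacks) and swarm lift-off signatures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
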