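Package: swmar
Title: Stationary Wavelet Movement-Artifact Reduction for Ambulatory ECG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and removes movement artifacts from ambulatory
    electrocardiograms using a synchronously recorded triaxial
    accelerometer. Implements the SWMAR pipeline: band-pass
    preprocessing, an energy-of-second-derivative QRS detector, robust
    MAD-based motion detection on the acceleration module, a stationary
    (undecimated) Haar wavelet decomposition with per-level robust
    coefficient thresholds, and reconstruction/subtraction of the
    artifact waveform. Includes a normalized LMS adaptive-filter
    comparator, a ground-truthed synthetic generator emulating equine
    ambulatory recordings, and an evaluation harness (movement-artifact
    percentage, Bland-Altman agreement).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
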