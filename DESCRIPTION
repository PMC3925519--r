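Package: eegseize
Title: Wavelet-Feature Detection of Epileptic Seizure Events and Onsets in EEG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Discrete wavelet (Daubechies-2) decomposition of EEG signals,
    subband and raw-epoch feature extraction (energy, entropy, moments,
    interquartile range, mean absolute deviation), a linear classifier for
    three-class seizure event detection, and an epoch-wise channel-voting
    seizure onset detector scored by latency, sensitivity and false-detection
    rate. Includes readers for single-column ASCII and EDF records, a seeded
    synthetic EEG generator for both record styles, and command-line entry
    points for the full pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: stats, utils, signal, jsonlite
Suggests: testthat (>= 3.0.0), MASS, optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
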