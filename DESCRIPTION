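Package: gcscreen
Title: Suspect Screening for GC-EI-HRMS with Accurate-Mass Spectral Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A gas chromatography electron-ionization high-resolution mass
    spectrometry (GC-EI-HRMS) suspect-screening engine. Converts profile
    spectra to centroids, builds extracted-ion chromatograms, deconvolutes
    co-eluting signals into components, scores component spectra against
    accurate-mass EI libraries with a pure-weight-factor weighted
    forward/reverse match factor and a trapezoidal Kovats retention-index
    penalty, and provides the evaluation machinery (false-positive /
    false-negative scoring, match-factor cutoff calibration, accurate-mass
    tolerance and pure-weight-factor sweeps, screening-detection-limit
    estimation) together with a synthetic-data generator that makes the whole
    pipeline testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils
Suggests:
    mzR,
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
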