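Package: sleepdev
Title: Pediatric Sleep-EEG Architecture and Brain-Age Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing pediatric polysomnography: reading EDF
    recordings and hypnograms, preprocessing (contralateral-mastoid
    referencing, resampling, zero-phase filtering, spectrum-interpolation
    line-noise removal), Hjorth-parameter artifact rejection, sleep
    macro-architecture metrics, Welch band power, Morlet-wavelet sleep
    spindle detection (slow and fast classes), zero-crossing slow
    oscillation detection under relative or absolute amplitude thresholds,
    permutation-calibrated slow-oscillation/spindle phase coupling, and a
    linear brain-age model with brain-age-gap group analysis. Includes a
    ground-truthed synthetic PSG generator for validating every stage of
    the pipeline without access-controlled clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
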