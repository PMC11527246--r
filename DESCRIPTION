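Package: esgtools
Title: Multichannel Electrospinography: Artifact Removal, Spatial
    Filtering, and Evoked-Response Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for extracting somatosensory evoked potentials from
    noninvasive multichannel spinal cord (electrospinography) and EEG
    recordings. Provides stimulation-artifact interpolation, zero-phase
    Butterworth/notch/comb filtering, resampling, threshold-based artifact
    rejection, cardiac-artifact removal via a per-channel optimal basis set
    around detected R-peaks, canonical-correlation-average-regression (CCAR)
    spatial filters for single-trial evoked-response extraction,
    peak/latency/SNR metrics, time-frequency maps, the interaction-ratio
    integration statistic, spatiotemporal cluster-based permutation tests,
    noncentral-t power analysis, and Monte-Carlo robustness curves. A
    synthetic-data module generates grid recordings with planted dipolar
    evoked responses, cardiac artifacts, stimulation transients, and
    structured noise, with ground truth, so the whole chain is testable
    without external data. Reads and writes BrainVision recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    pracma,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
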