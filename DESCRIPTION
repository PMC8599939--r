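Package: eegvigor
Title: EEG Spectral and Bispectral Biomarkers of Motor Vigor
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deriving cortical EEG biomarkers of motor vigor (the
    inverse of the time from a Go cue to peak squeeze-bulb force). Implements
    a zero-phase FIR and stationary-wavelet EEG conditioning chain, a
    53-feature-per-channel bank of relative band powers, harmonic parameters,
    and bispectral amplitudes and phases over the six standard EEG bands,
    bootstrapped LASSO prediction of motor vigor with band-restricted model
    comparison, and the accompanying inferential layer (Fisher z, mixed
    ANOVA with Greenhouse-Geisser correction, t-tests, Bonferroni). Includes
    a synthetic cohort generator with planted, recoverable feature-vigor
    coupling for calibration and testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    signal,
    jsonlite,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
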