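Package: dirlfp
Title: Directional Local Field Potentials for Deep Brain Stimulation Programming
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of intraoperative local field potentials (LFPs) recorded
    from the segmented contacts of directional deep brain stimulation (DBS)
    leads in the subthalamic nucleus. Computes a normalized beta-band (13-35 Hz)
    statistic per directional contact from Welch power spectra with spectral
    peak detection over a 1/f background, scores contacts from monopolar-review
    tables (clinical efficacy in percent rigidity improvement per mA and
    therapeutic window in mA), ranks contacts, and quantifies the predictive
    value of LFP-guided contact screening against a uniform-random baseline via
    top-k prediction-probability curves and paired group statistics. Includes a
    synthetic cohort generator that couples directional beta power and clinical
    response to a common beta source, so the full pipeline is testable without
    patient recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    signal,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
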