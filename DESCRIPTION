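Package: pulsemap
Title: Pulsatile Feature Maps from Facial Video for Remote Physiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for camera-based photoplethysmography (rPPG) on short
    multispectral facial video clips: facial region-of-interest cropping,
    skin segmentation with chin-stand suppression and head-movement
    rejection, clip-level heart-rate estimation from per-pixel spectral
    analysis of the green channel, detection of heartbeat peaks and
    troughs in the spatially pooled pulsatile signal, extraction of
    pulsatile image stacks, and computation of the physiological feature
    maps I_AC (pulsatile amplitude) and I_R (log-ratio absorption
    amplitude).  Includes a Beer-Lambert-based synthetic facial-video
    generator with known ground truth and a subject-grouped
    cross-validation harness with a weighted-loss classifier for
    emotion-state experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
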