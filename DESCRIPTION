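Package: pphevents
Title: Detection and Quantification of Endocytic Scission Events in
    Pulsed-pH TIRF Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An automated analysis pipeline for pulsed-pH (ppH) TIRF
    time-lapse recordings of clathrin-mediated endocytosis. Frames
    acquired alternately at extracellular pH 7.4 and pH 5.5 are
    demultiplexed; diffraction-limited fluorescent objects are detected
    per frame with an a-trous B-spline wavelet decomposition and local
    standard-deviation thresholding, linked into tracks, and screened
    with rule-based criteria for candidate scission events (newly
    internalized, pHluorin-positive vesicles). A support vector machine
    sorts candidate patches into bona fide events and false positives.
    Fluorescence traces are measured with annulus background
    subtraction, aligned and averaged, corrected for spectral
    bleed-through, and compared with shift-based null envelopes.
    Event-frequency statistics (cumulative curves, whole-cell over
    cell-attached frequency ratios, cluster densities) quantify
    endocytic activity. Equilibrium one-site hyperbola and 1:1 Langmuir
    kinetic binding models are fitted to ELISA curves and SPR
    sensorgrams. A synthetic-data module generates ppH movies,
    sensorgrams, binding curves and event streams with known ground
    truth so that every stage of the pipeline can be validated without
    experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    minpack.lm,
    EBImage,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
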