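Package: camoquant
Title: Quantifying Background-Matching Camouflage Through Predator Vision
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying how well a prey animal matches its visual
    background through the eyes of its predators, and for relating camouflage
    metrics to field predation outcomes. Implements receptor-noise-limited
    (log-form) chromatic and achromatic discrimination for tetrachromatic
    avian vision, quantum-catch computation from reflectance spectra or
    calibrated channel images, Gaussian acuity control (blur and rescale for
    a given spatial acuity and viewing distance), octave-spaced granularity
    analysis with pattern-energy-difference scoring, and survival analysis
    (Kaplan-Meier, Cox proportional hazards, pairwise log-rank) of
    interval-checked predation experiments. A synthetic-data module generates
    lichen-, bark- and moth-like textures, receptor sets, spectra and
    predation event tables so the full pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
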