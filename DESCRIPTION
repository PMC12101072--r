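Package: specslope
Title: Spectral-Slope Statistics of Animal Colour Patterns and Natural Scenes
Version: 0.1.0
Authors@R: person("Pattern", "Statistics Lab", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing the second-order (Fourier) image statistics of
    animal colour patterns with those of natural scenes. Converts multispectral
    image stacks to computational-receptor views, preprocesses them (dark-noise
    subtraction, exposure-stability QC, saturated-pixel repair, grey-standard
    normalisation, Naka-Rushton excitation), extracts analysis squares
    (largest square inscribed in a body mask, or a centred scene crop),
    measures the spectral slope of the rotationally averaged Fourier amplitude
    spectrum with standardised frequency bounds and log-binning, computes
    physical-unit acuity limits, and contrasts group slope distributions with a
    hierarchical Bayesian Gaussian model (sex effect with species-level random
    intercepts and slopes, plus a region model for scenes). Includes a fully
    seeded synthetic-data generator (power-law images of known exponent,
    abdomen-like masks, multispectral stacks, hierarchical cohorts) so every
    stage is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr
Config/testthat/edition: 3
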