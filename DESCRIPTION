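Package: geniculate
Title: Characterization of Visual Response Properties of LGN Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for characterizing visual responses of neurons
    in the lateral geniculate nucleus (LGN) from extracellular spike trains.
    Synthesizes drifting-grating, full-field flicker, and contrast-modulated
    spatiotemporal noise stimuli; estimates spatial receptive fields by
    spike-triggered averaging with 2D Gaussian fits; fits difference-of-Gaussians
    spatial-frequency, two-half-Gaussian temporal-frequency, and hyperbolic
    (Naka-Rushton) contrast-response tuning curves; computes direction and
    orientation selectivity indices, F1/F0 linearity, and transient/sustained
    indices; and aggregates per-unit results into population summaries with
    the appropriate parametric or non-parametric group comparisons. Includes
    a linear-nonlinear-Poisson (LNP) model-neuron simulator with full ground
    truth so every stage of the pipeline can be validated by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
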