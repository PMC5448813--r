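Package: bistapc
Title: Predictive-Coding Modelling of Bistable Perception
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling bistable perception as precision-weighted
    Bayesian belief updating driven by prediction errors. Implements a
    per-overlap belief-update engine for ambiguous structure-from-motion
    stimuli (stability prior, stereodisparity weight, bimodal likelihood),
    simulation of perceptual time-courses and dominance-phase statistics,
    MAP model inversion with Laplace model evidence, random-effects Bayesian
    model selection (exceedance and protected exceedance probabilities),
    canonical rival models of bistability (oscillator, attractor,
    intermediate), and model-based fMRI design construction with voxel-wise
    Bayesian model comparison. Includes a synthetic-cohort generator
    emulating a 20-subject ambiguous/replay block design so that every
    stage is exercisable without real data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    fitdistrplus
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
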