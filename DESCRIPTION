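Package: xmcue
Title: Crossmodal Cue-Predictability Learning and Integration Models for
    Location-Cueing Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for trial-wise computational analysis of crossmodal
    spatial-attention expectancies in multisensory location-cueing (Posner)
    paradigms. Implements a Beta-Bernoulli ideal observer that learns the
    cue validity separately for visual and tactile targets, a weighted
    linear integration of the two modality-specific predictabilities
    (weighting factor w), and a linear response-speed observation model
    whose parameters are estimated per subject by profiled maximum
    likelihood. Includes an alternative block-constant predictability
    model, random-effects Bayesian model selection with protected
    exceedance probabilities, seeded generators for the experimental
    designs and synthetic cohorts with known ground truth, and parameter-
    and model-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
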