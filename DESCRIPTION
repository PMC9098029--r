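Package: painscales
Title: Multi-Scale Multivariate Decoding of Evoked Pain Intensity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how much decodable information about evoked pain
    intensity is carried by brain activity at different anatomical scales.
    Given trial-level beta maps and pain ratings from multiple studies (real
    NIfTI data or the built-in synthetic multi-study generator), the package
    standardizes images and ratings, collapses trials to rating quartiles,
    trains principal-component-regression decoders over six model spaces
    (single region, fine and coarse resting-state networks, two multisystem
    masks, and the full brain) with participant-grouped, study-balanced
    repeated nested cross-validation, and compares scales with linear
    mixed-effects models, planned orthogonal contrasts, and Bayes factors.
    It also characterizes the resulting decoders via bootstrap weight-map
    stability, within-participant mediation of experimental factors,
    behavioral variance decomposition, and specificity tests against
    non-pain task maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    lme4,
    lmerTest,
    MASS,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
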