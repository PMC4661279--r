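Package: ambicon
Title: Choice Modelling and fMRI Analysis of Decisions Under Ambiguity and Informational Conflict
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying decision making when outcome probabilities are
    imprecise (ambiguity) or described by disagreeing sources (informational
    conflict). Implements a matched-gamble card-deck task design with
    parametrically varied uncertainty levels, a subjective-expected-utility
    multinomial logit choice model with condition-specific probability
    weighting, per-subject maximum-likelihood parameter estimation, model-free
    attitude scores, group behavioural statistics, synthetic cohort / choice /
    BOLD data generators with planted ground-truth effects, voxelwise general
    linear model estimation with a double-gamma haemodynamic response, group
    random-effects and brain-behaviour maps, Monte-Carlo cluster-extent
    thresholding, and a split-half out-of-sample region-of-interest
    confirmation procedure.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    RNifti
Config/testthat/edition: 3
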