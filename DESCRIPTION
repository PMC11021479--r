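Package: piriform
Title: Feedforward and Feedback Odor Representations in the Olfactory Bulb
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for comparing odor representations carried by olfactory
    sensory neurons (feedforward) and piriform-cortex feedback axons imaged
    in the olfactory bulb. Implements the calcium-response analysis pipeline
    (blank-trial significance classification, response-polarity classes,
    lifetime and population sparseness, ranked tuning curves,
    representational similarity, trial reliability, and mixture-overlap
    comparisons), a Monte-Carlo null model for response polarity with an
    exact analytic counterpart, a bulb-to-cortex rate model with global
    activity-dependent inhibition that produces nonmonotonic concentration
    tuning, and synthetic response-tensor generators that emulate the
    statistical structure of calcium-imaging data for both populations.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
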