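Package: icusurv
Title: Multimodal Deep Survival Modelling for ICU Mortality
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Survival analysis of in-ICU mortality from multimodal patient
    data. Implements Cox proportional-hazards machinery (Breslow/Efron
    partial likelihood, Newton-Raphson fitting with Wald inference, Breslow
    baseline survival), a DeepSurv-style neural risk model with early
    average fusion of text and image hidden features alongside SAPS-II risk
    factors, feature encoders including average pooling of token embeddings
    and a graph convolutional network over a radiology finding graph, a
    concordance-index and bootstrap evaluation protocol with paired model
    comparison, and a seeded synthetic cohort generator (including a SAPS-II
    scorer) so the full pipeline is testable without access to restricted
    clinical databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
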