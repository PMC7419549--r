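Package: cfdiag
Title: Counterfactual Diagnosis over Noisy-OR Disease Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for causal and counterfactual differential diagnosis on
    three-layer (risk factor, disease, symptom) noisy-OR Bayesian networks
    treated as structural causal models. Ranks candidate diseases by expected
    disablement (how many present symptoms would switch off if the disease
    were cured) and expected sufficiency (how many present symptoms would
    persist if every other cause were switched off), computed both by an exact
    closed form and by twin-network counterfactual inference, with an
    abduction-action-prediction oracle for verification. Includes exact
    associative (posterior) inference, a synthetic clinical-vignette
    simulator, cohort evaluation metrics (top-k accuracy, error reduction,
    rank comparison, rarity stratification, matched differential size), and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
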