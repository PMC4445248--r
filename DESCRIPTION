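Package: ctxfear
Title: Bayesian Context Fear Conditioning Automaton
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete-event simulation of contextual fear learning by a
    mode-switched cortical-hippocampal-amygdala network. Contexts are sets
    of attributes sampled serially without replacement; a dentate/CA3
    K-winners-take-all circuit creates, completes and updates sparse
    context representations, and an exact Bayesian weight of evidence
    (log10 odds of hypergeometric observation models) gates representation
    creation, updating, amygdala conditioning and fear expression.
    Includes a synthetic context-ensemble generator with controlled
    pairwise similarity, lesion switches for the dentate pathway, and
    scripted replications of pattern-separation, immediate-shock-deficit,
    generalization and fear-misattribution experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
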