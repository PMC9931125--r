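Package: netmoa
Title: Ensemble Network Models of Drug Mechanism of Action
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Constraint-trained ensemble modelling of drug mechanism of
    action over directed protein-protein interaction networks. Signal is
    propagated from clamped drug targets through weighted links; link
    weights are sampled by simulated annealing against a truth table of
    stimulus-response rules, and only solutions above an accuracy
    threshold are retained in the model ensemble. Ensemble activity
    profiles are summarised per pathophysiological motive as effector
    reversal counts, T-Signal and W-Signal intensities, drug-combination
    synergy calls, modulation classes, and high-support mechanism-of-action
    path subgraphs, with hypergeometric over-representation analysis of
    up- and down-regulated protein sets. Includes a synthetic fixture
    generator with planted mechanisms for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    yaml,
    fgsea,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
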