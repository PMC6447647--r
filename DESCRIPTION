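Package: assimnet
Title: Cell-Assembly Assimilation in Plastic Rate Networks and
    Spontaneous-Acquisition Behavioral Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a recurrent excitatory/inhibitory rate network with
    threshold-linear activation, Bienenstock-Cooper-Munro (BCM) synaptic
    plasticity with a sliding modification threshold, and homeostatic synaptic
    scaling, and measures how strongly newly inserted three-neuron cell
    assemblies are assimilated as a function of their activity correlation with
    the rest of the network. Also provides the companion behavioral analysis
    toolkit for word-acquisition/essay-production experiments: essay-length
    normalization, confidence-band filtering, Mann-Whitney/t comparisons with
    probability-of-superiority and Cohen's d effect sizes, bootstrap confidence
    intervals, two surrogate-data tests (confidence/length dot-product shuffle
    and letter-reassignment), a word2vec-format embedding reader with an
    essay-to-component semantic similarity score, and a synthetic-data
    generator with controllable planted effects for calibration and power
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
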