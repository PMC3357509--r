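Package: angn
Title: Artificial Neuron-Glia Networks Trained by Genetic Algorithms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Feed-forward multilayer networks augmented with artificial
    astrocytes that monitor neuronal firing over repeated pattern
    presentations and potentiate or depress connection weights through six
    counter-based neuron-glia plasticity rules. Networks are trained by a
    hybrid scheme: an unsupervised astrocyte phase computes the error signal
    and a real-coded genetic algorithm (fitness-proportionate selection,
    single-point crossover, replace-worst substitution) evolves the initial
    weights. Includes a multiplexer truth-table generator, tabular dataset
    loading with min-max normalisation, stratified splits, and an experiment
    runner comparing the plain network against the six neuron-glia variants.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
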