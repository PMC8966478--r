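Package: cagen
Title: Counterfactual Activation Generation for Brain-Decoding Classifiers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Counterfactual explanation of convolutional classifiers of 2D
    brain-activation maps. Trains a multi-domain conditional image translator
    (a StarGAN-style generator with Wasserstein-GP adversarial, domain
    classification, cycle-consistency, and frozen-classifier guidance losses)
    and uses it to build counterfactual explanations of correct and incorrect
    classifications, percentile-perturbation robustness sweeps, class-mean
    difference controls, and counterfactual exaggeration with texture-feature
    extraction and injection testing. Includes a synthetic multi-class
    activation-map generator, a small from-scratch CNN task classifier, and a
    reverse-mode automatic-differentiation engine supporting the second-order
    gradients required by the gradient penalty.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
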