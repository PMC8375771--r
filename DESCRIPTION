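Package: advrep
Title: Representational Analysis of Adversarially Perturbed Images in
    Networks and Synthetic Visual Cortex
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for comparing neural representations of regular and
    adversarially perturbed images across a hierarchical image classifier
    and a simulated visual cortical sheet. Provides a small trainable
    eight-stage convolutional surrogate classifier with per-stage
    activations and input gradients, generators for adversarial-noise
    (activation-maximization) and adversarial-interference (accept/reject
    hill-climb) images, representational similarity analysis with
    bootstrap and permutation inference and Mann-Kendall trend tests,
    searchlight maps on flattened cortical sheets, split-half
    consistency-based vertex selection, sparse forward encoding models
    fitted by regularized orthogonal matching pursuit, and a synthetic
    data generator with recorded ground truth for recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    png
Config/testthat/edition: 3
RoxygenNote: 7.3.3
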