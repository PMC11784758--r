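Package: gmvo
Title: Gradient Multi-Verse Optimizer for Training Small Neural Classifiers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Implements the multi-verse optimizer (MVO) and its hybrid
    gradient variant (GMVO), population metaheuristics that search a bounded
    box by exchanging variables between candidate solutions through
    white/black-hole tunnels and jumping near the incumbent best through
    wormholes, with the wormhole step size scaled per dimension by a
    finite-difference estimate of the gradient direction. Includes a small
    feed-forward network whose flattened weight vector is the search
    variable, stochastic gradient descent with momentum and ADAM baselines
    trained by exact backpropagation, a preprocessing pipeline for the
    Wisconsin breast-cancer tabular datasets (missing-value imputation,
    label encoding, min-max normalization, stratified splits, k-fold
    indices) together with a synthetic two-class generator emulating their
    structure, six confusion-matrix classification metrics including the
    Matthews correlation coefficient, a Wilcoxon rank-sum comparison of
    repeated runs, and a reproducible multi-run experiment harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
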