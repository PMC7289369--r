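Package: evobci
Title: Evolutionary Optimization of Shallow Neural Classifiers for Motor-Imagery EEG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for classifying motor-imagery EEG with purposely shallow neural
    networks tuned by genetic algorithms. Implements discrete-wavelet-transform
    variance feature extraction from segmented multichannel trials, a genetic
    wrapper feature selector over binary masks, a two-step evolutionary
    hyperparameter search (network structure first, then learning parameters)
    for feed-forward, one-dimensional convolutional and gated-recurrent-unit
    classifiers, Cohen's Kappa evaluation over repeated runs, and a model
    comparison suite combining the Friedman test, Holm-adjusted Wilcoxon
    signed-rank post-hocs and a count-based Bayesian signed-rank test with a
    region of practical equivalence. A seeded synthetic generator of
    ERD-modulated EEG-like trials and feature fixtures makes every stage
    testable without recorded data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    glmnet,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
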