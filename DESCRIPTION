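Package: bcsyolo
Title: Lightweight Star-Attention Object Detection for Dairy Cow Body Condition Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds, trains, profiles and evaluates a family of lightweight
    single-stage object detectors for automated body condition scoring (BCS)
    of dairy cows from overhead tail-region images. Implements the star
    operation feature blocks (element-wise products of linearly transformed
    features), efficient multi-scale attention (EMA) with grouped directional
    pooling, a shared GroupNorm lightweight detection head (SSLDH) with
    distribution-based box regression, channel-wise knowledge distillation
    between teacher and student detectors, deterministic architecture
    profiling (parameters, FLOPs, half-precision checkpoint size), detection
    metrics (precision, recall, AP, mAP over IoU sweeps), and a fully
    self-contained synthetic overhead-image dataset generator with a
    motion-blur robustness harness. The network engine (grouped convolutions
    with reverse-mode gradients, batch and group normalization, SGD training)
    is implemented in C++ via Rcpp and BLAS.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    png,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
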