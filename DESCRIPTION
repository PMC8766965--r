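Package: sbcnn
Title: Stochastic Binarized Convolutional Neural Networks for Near-Sensor Image Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Toolkit for fully binarized convolutional neural networks whose
    input layer is computed by stochastic bitstream sampling from a normal
    distribution. Provides bit-packed {-1,+1} tensor arithmetic
    (XNOR/popcount neurons with learned integer thresholds), per-channel
    mean-sigma normalization and stochastic binarization with configurable
    presentation counts, binarization-aware training with the
    straight-through estimator and Adam, batch-norm folding to an
    integer-only inference path, a sliding-window heatmap detector for
    locating small high-contrast objects in microscopy-like images, an
    in-memory-computing hardware cost model (weight memory, operation
    counts, 32x32 crossbar tile mapping, energy), synthetic scene and
    classification data generators, and ROC/PR/mAP evaluation with
    multi-trial averaging.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, jsonlite
Suggests: testthat (>= 3.0.0), pROC, png, optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
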