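# sbcnn — stochastic binarized CNNs for near-sensor image analysis

Binarized neural networks (BNNs) restrict weights and activations to
{−1,+1}, collapsing each multiply-accumulate into an XNOR plus a population
count against a learned integer threshold:

    y = sign( popcount(XNOR(w, x)) − b )

which equals the ±1 dot product thresholded at 2b − n. In practice the
*input* layer of a hardware BNN stays in int8 or float because camera
pixels are not binary. A **stochastic binarized CNN (SBCNN)** binarizes the
input too: pixels are standardized per channel, X_r = (X_d − μ)/σ, and each
of N_pre *presentations* draws one bit per pixel by comparing X_r against a
standard-normal threshold, so P(bit = 1) = Φ(X_r). A resistive-memory
(OxRAM) comparator provides that normal threshold physically through its
cycle-to-cycle resistance variability, making the whole pipeline — input
sampling included — implementable in a crossbar of differential 2T-2R
bitcells.

This package is for people studying that compute model: it provides

* bit-exact packed {−1,+1} tensor arithmetic (`binary_tensor`, `xnor`,
  `popcount`, `binary_neuron`);
* the stochastic input front end (`channel_stats`, `normalize_channels`,
  `sample_bit`, `sample_stream`, a behavioural OxRAM threshold source);
* binarization-aware training (straight-through estimator, Adam, batch
  norm) for small conv/pool/fc networks, `sbcnn_train`;
* export to an integer-only inference form (`export_model`) with batch norm
  folded into exact integer thresholds, and Algorithm-style stochastic
  inference with presentation aggregation (`sbcnn_infer`);
* a sliding-window heatmap detector for small high-contrast objects in
  microscopy-like images (`detect_objects`, `nms`, `match_detections`);
* a hardware cost model: parameter/memory accounting per precision,
  operation counts, 32×32 crossbar tile mapping and energy estimates
  (`weight_memory`, `count_ops`, `map_to_tiles`, `energy_estimate`);
* synthetic data generators for scenes, labelled slices and multi-class
  classification sets (`generate_scene`, `make_slices`,
  `generate_classification_set`);
* evaluation: ROC/AUC, precision-recall/mAP, multi-trial averaging
  (`roc_curve_auc`, `pr_curve_map`, `run_trials`, `evaluate_strategies`).

## Worked example

Train a small binarized classifier on a synthetic three-class set, export
it to integer-only form and run stochastic inference with 8 presentations:

```r
library(sbcnn)
set.seed(42)
ds  <- generate_classification_set(n_classes = 3, n_per_class = 120,
                                   image_size = 16)
tr  <- 1:240; te <- 241:360
net <- sbcnn_train(build_small_cnn(3, 16), ds$x[, , , tr], ds$y[tr],
                   presentation_config(8), epochs = 10, seed = 7)
model  <- export_model(net)
scores <- sbcnn_infer(model, ds$x[, , , te], n_infer = 8, seed = 99)
multiclass_metrics(scores, ds$y[te])
#> accuracy      map  roc_auc
#>        1        1        1
```

`scores` is an integer matrix (one row per image, one column per class) —
after export no floating-point value influences the ranking. On this easy
separable set the classifier is perfect; the interesting dial is `n_infer`,
which trades operations against score stability.

The pinned 2-class AlexNet architectures reproduce the published memory
accounting directly:

```r
full <- build_alexnet(2); red <- build_alexnet(2, reduced = TRUE)
weight_memory(full, "int8")    # 54.37 MiB
weight_memory(full, "fp32")    # 217.48 MiB
weight_memory(red,  "binary")  # 4.796 MiB
memory_savings(full, "fp32", red, "binary", round_headline = TRUE)  # 45
memory_savings(full, "int8", red, "binary", round_headline = TRUE)  # 11
```

A thin CLI over the same functions lives in `inst/scripts/sbcnn`
(`cost`, `synth`, `detect`, `eval` subcommands).

See `vignettes/sbcnn-methods.Rmd` for the model, the training method, the
exact batch-norm folding argument, detector calibration and the cost-model
conventions.

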