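---
title: "Stochastic binarized CNNs: model, training and hardware cost"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic binarized CNNs: model, training and hardware cost}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sbcnn)
```

## The model

A binarized neural network (BNN) constrains every weight and activation to
$\{-1,+1\}$, so each neuron reduces to an XNOR of bit-vectors followed by a
population count against a learned integer threshold $b$:

$$y = \mathrm{sign}\big(\mathrm{popcount}(\mathrm{XNOR}(w, x)) - b\big),$$

which is algebraically the $\pm 1$ dot product thresholded at $2b - n$ for
fan-in $n$. Hardware BNNs usually keep the *input* layer in int8 or float
because camera pixels are not binary. The stochastic binarized CNN (SBCNN)
closes that gap: pixels are standardized per channel,
$X_r = (X_d - \mu_i)/\sigma_i$, and each presentation of the image draws one
binary sample per pixel by comparing $X_r$ against a standard-normal
threshold, so $P(\text{bit}=1) = \Phi(X_r)$. Averaging $N_{pre}$ independent
presentations gives a bitstream mean $X_m$ whose expectation is $\Phi(X_r)$
and whose variance decays as $1/N_{pre}$. A uniform-threshold variant
(pixels min-max rescaled to $[0,1]$, compared against a uniform draw) is
included as the stochastic-computing baseline. Physically, the normal
threshold is what a resistive-memory comparator provides for free: the
cycle-to-cycle variability of an OxRAM cell's low-resistance state is
approximately normal, and `device_threshold_sequence()` models exactly that
(a truncated-normal resistance mapped through a monotone voltage mapping) —
with an affine mapping it reproduces the normal sampler.

Inference aggregates presentations after the first layer: each presentation's
binarized input passes the first conv layer to a sign map $a_n$, the maps are
combined by an elementwise majority $A_0 = \mathrm{sign}(\sum_n a_n)$, and
$A_0$ propagates through the remaining binary layers. Ties (even $N$, zero
sum) resolve to $+1$, matching the package-wide $\mathrm{sign}(0)=+1$
convention; the convention is ours — the method is silent on it — and is
applied identically in training and inference so exported decisions are
deterministic.

## Training

Training follows the standard binarization-aware recipe: real-valued shadow
weights are sign-binarized on every forward pass; the backward pass uses the
straight-through estimator with a hard-tanh window (gradients pass where the
pre-activation lies in $[-1,1]$ and are clipped elsewhere); Adam updates the
shadow weights, which are clipped to $[-1,1]$ after each step. Batch norm
follows each weight layer during training and is folded away at export.

The stochastic input layer re-samples its bitstream on every forward pass
with the configured $n_{train}$, so sampling noise acts as data augmentation
and the network adapts to the noise level it will see at inference. The
training loop feeds the presentation *mean* $X_m$ (rescaled to $[-1,1]$)
through the first layer rather than aggregating per-presentation sign maps;
because convolution is linear, the two differ only in where the
non-linearity is applied, and feeding the mean keeps the training cost
independent of $n_{train}$. $X_m$ is drawn directly as
$\mathrm{Binomial}(n_{train}, \Phi(X_r))/n_{train}$, an exact distributional
identity with averaging $n_{train}$ comparator draws.

Two presentation strategies are compared by `evaluate_strategies()`:
*matched* (train and infer with the same $N_{pre}$) and *max* (train at the
maximum presentation count, 256 by default, infer at smaller $N_{pre}$).
Whether batch-norm statistics should be re-estimated at the inference
presentation count under the max strategy is an open choice; we freeze them,
which is the conservative reading and requires no inference-time statistics.

## Integer-only export

`export_model()` folds each batch norm into one integer threshold per unit.
Writing the affine transform as $\gamma (s - \mu)/\sqrt{\sigma^2+\varepsilon}
+ \beta$ over the integer accumulation $s$, the sign decision is
$s \ge \theta$ for $\gamma > 0$ and $s \le \theta$ for $\gamma < 0$, with
$\theta = \mu - \beta\sqrt{\sigma^2+\varepsilon}/\gamma$. Because $s$ is an
integer, $\lceil\theta\rceil$ (respectively $\lfloor\theta\rfloor$)
reproduces the float decision *exactly* — we deliberately use the
ceiling/floor rather than nearest-integer rounding, which can flip decisions
whenever $s$ lands between $\theta$ and its rounded value. Two details are
worth recording:

* zero padding at conv borders means $s$ does not keep the parity of the
  fan-in there, so the threshold is stored in the accumulation domain
  rather than the popcount domain (the two are equivalent only at full
  fan-in parity);
* a max-pool sits between the accumulation and the comparison in our
  blocks, and pooling does not commute with weight negation
  ($\max(-s) = -\min(s)$), so negative $\gamma$ is handled by reversing the
  unit's comparison direction instead of negating its weights.

The folded path and the float reference path produce bit-identical
activations and class scores on every input, which the test suite checks on
thousands of random binary inputs, including networks with forced negative
batch-norm scales.

## Architectures

`build_alexnet()` pins the standard AlexNet body (224×224×3 inputs, five
conv layers, three fc layers, 57,012,034 parameters at 2 classes); the
*reduced* variant removes the middle 4096→4096 classifier layer
(16,781,312 parameters). These two specifications drive the memory and
operation accounting. The paper-scale architectures are not trained here:
desk-scale experiments use `build_small_cnn()`, a conv-pool-conv-pool-fc
binarized network for 16–32 px patches (~28k parameters) whose blocks are
ordered conv → pool → batchnorm → sign so that export stays integer-exact
(pooling acts on integer accumulations). Its `reduced` variant drops the
hidden fc layer, mirroring the depth reduction of the full model.

## Synthetic data

The generators produce statistical stand-ins, not photorealistic microscopy:

* **Scenes** (`generate_scene()`): a background of mean color, low-frequency
  mottling and iid Gaussian noise, with non-overlapping parametric objects
  (disks, rods or ellipses) whose color sits a configurable Mahalanobis
  distance (default 6 background-noise units) from the background mean.
  Defaults — 160 px fields, 4 objects of 11–16 px — keep the object density
  of the same order as stained-smear fields imaged at high magnification,
  where pathogen objects are sparse high-contrast blobs; real data are
  denser in texture and far more variable in stain and focus, so passing
  detection tests here demonstrates the pipeline's mechanics, not clinical
  performance.
* **Slices** (`make_slices()`): positives are crops centered on ground-truth
  boxes, augmented by the 8-element dihedral group ("rotation and flipping"
  is not further specified by the method we follow, so we take all four
  right-angle rotations with and without a flip). Each dihedral copy is
  drawn at a random offset of up to `jitter` pixels (default 3, capped so
  the patch center stays inside the box): a sliding window sees objects
  off-center, and a classifier trained only on perfectly centered crops
  loses sensitivity beyond ~6 px of offset, which measurably costs
  detection recall. The default matches the worst-case offset between an
  object center and the nearest window center at the detection stride of
  5; larger jitter makes the classifier so translation-tolerant that the
  response plateaus of neighbouring objects merge into one candidate
  region. Negatives are random non-intersecting crops kept with
  probability `neg_keep_prob` (default 0.5; the rebalancing target is not
  specified in the source method, so the probability is exposed).
  Downsampling uses area averaging.
* **Classification sets** (`generate_classification_set()`): smooth random
  color-texture templates rescaled so the minimum pairwise RMS distance
  equals `separation`, plus iid pixel noise. The default
  separation/noise ratio of 4 makes the Bayes error negligible — the
  strategy experiments probe the *stochastic-input* degradation, not the
  intrinsic difficulty of the task.

## The sliding-window detector

Windows of the classifier's input size slide with stride
$\text{window}\times(1-\text{overlap})$ (the published setting is 50%
overlap; border windows snap inside the image). Each window's positive-class
score is added to every pixel it covers, giving the heatmap. The patch
scorer squashes the integer score margin through a logistic at the training
temperature $\sqrt{\text{fan-in}}$, so scores live in $[0,1]$: with signed
margins, the lower window coverage at image borders turns uniformly negative
background into spurious hot zones after normalization.

The source method says only that heatmaps are "normalized, followed by a
threshold operation" and that boxes come from contour detection; the
concrete scheme here is ours and went through a deliberate calibration on
pilot scenes:

1. normalize each pixel by its window coverage (mean covering-window
   probability — an absolute scale, available as `method = "coverage"`;
   global min-max remains available as `method = "minmax"`);
2. mark coarse candidate regions at a low absolute floor (default 0.25);
3. within each 8-connected coarse component, keep pixels scoring at least a
   fraction (default 0.65) of that component's own peak — peak-relative
   trimming decouples each object from the scene's strongest response and
   recovers the tight plateau around the object center;
4. extract tight bounding boxes of the resulting fine components, dropping
   fragments below a minimum area (default the squared stride), score each
   box by its mean normalized heat, and apply greedy NMS (IoU 0.3).

A single global min-max threshold — the naive reading of "normalize then
threshold" — couples every object to the scene's best-responding object:
on pilot scenes ~25% of true objects fell below half of the global maximum
purely through window-grid alignment. The two-level scheme above removed
that failure mode without touching the classifier. Localization resolution
is set by the stride, since all pixels in a stride cell share the same
covering windows: boxes are quantized to the stride grid. The detection
experiments therefore run at 75% overlap (stride 5 for a 20 px window),
trading 4× more window evaluations for ~2× finer boxes; the CLI default
stays at the published 50%.

Boxes are 0-based, half-open $[x_0,x_1)\times[y_0,y_1)$ throughout, with
$x$ as column and $y$ as row; conversions happen only at I/O boundaries.

## Hardware cost model

`count_params()`/`weight_memory()` account conv layers as
$C_{out}C_{in}k^2(+C_{out})$ and fc layers as $n_{in}n_{out}(+n_{out})$
parameters, at 4 bytes (fp32), 1 byte (int8) or 1/8 byte (binary, per-layer
ceiling to whole bytes). Memory is reported in binary mebibytes ($2^{20}$
bytes): under the pinned 2-class architectures this convention reproduces
the int8 reference value (54.37) exactly and the fp32/reduced-binary values
to ≤0.2%, which decimal megabytes do not. Bias parameters are counted at
the layer's weight precision. The headline ratios follow directly:
full-fp32/reduced-binary ≈ 45 and full-int8/reduced-binary ≈ 11.

`count_ops()` counts one MAC (or XNOR-accumulate) per weight per output
position; with stochastic input, the first layer's operations and one
sampling operation per input value scale by $N_{pre}$. `map_to_tiles()`
models the in-memory-computing fabric: a 32×32 grid of 32×32 differential
bitcell tiles, block matrix multiplication with 32-wide blocks, one row per
cycle (32 cycles per resident pass), extra passes when the block count
exceeds the 1024-tile capacity, and one 5-bit partial-sum lookup table per
block. `energy_estimate()` is a plain linear functional over an
`energy_table()`; the shipped constants are illustrative placeholders —
absolute energies are configuration, not claims, and platform reference
values (GPU, ASIC accelerators) are cited constants outside the model.

## Numerical and design choices

* $\mathrm{sign}(0) = +1$ everywhere (binarization, presentation ties,
  thresholds); makes every decision deterministic.
* Bit packing uses 8-bit bytes, little-endian bit order within each byte
  (the order of R's `packBits`), padding bits stored as zero and masked out
  of every popcount. The packed container stores weights column-major as
  hex strings with a JSON header; the loader validates payload length and
  padding before unpacking.
* Channel statistics are population (ddof 0) moments over the training
  split; constant channels are an error directing the caller to a floor
  value rather than silently producing infinities.
* The printed form of the binarization rule compares the *normalized* pixel
  against a normal draw with *raw-domain* channel parameters, which would
  saturate for 0–255 pixel statistics; we implement the self-consistent
  reading (raw pixel vs raw-parameter normal, equivalently normalized pixel
  vs standard normal) and expose the literal form behind
  `sample_bit(..., literal = TRUE)` for inspection.
* ROC curves sweep distinct score values with ties grouped; AUC is the
  trapezoid area and equals the Mann–Whitney statistic. Average precision
  integrates the precision envelope over recall (all-points
  interpolation); the interpolation convention is ours, as mAP is named
  but not defined in the source method. An AUC of 0.5 is *uninformative*,
  not "worst" — a systematically inverted classifier scores below 0.5.
* Training divergence (non-finite loss) raises an error naming the epoch
  rather than returning a broken model.

## Problem sizes

The shipped experiments are deliberately desk-scale: classification sets of
a few hundred 16 px images, three-class strategy grids over
$N_{pre}\in\{2,8,32\}$ with 5 trials, and twenty 160 px scenes with ~100
planted objects for the detection study, with the mini architectures above.
Full-scale runs (CIFAR-10, the Makerere microscopy corpus, the 224 px
AlexNet variants) use the same code paths — `scripts/full_scale_cifar.R`
sketches the configuration — but their published accuracies are not
reproduced at this scale, and nothing in the test suite asserts them.

## Known limitations

* The training engine targets small conv/pool/fc networks; it has no GPU
  path, no dilation/grouping, and max pooling assumes non-overlapping
  windows during training (inference pooling is general).
* Stochastic inference cost grows linearly in $N_{pre}$ for the first
  layer; the package exploits the binomial shortcut only where the mean is
  sufficient (training), never in the per-presentation inference path.
* The device noise model is behavioural: a truncated-normal threshold
  source. Electrical non-idealities (read disturb, drift, endurance) are
  out of scope.
* Detection defaults were calibrated on the synthetic scene family; other
  object scales or densities will need their own floor/threshold choices.
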