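---
title: "Classifying duck-egg candling images: model, preprocessing and protocol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying duck-egg candling images: model, preprocessing and protocol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eggcandler)
```

## The problem

Hatcheries candle incubated duck eggs around embryonic day 12 to remove
non-viable eggs: transilluminating each egg with a bright light and
judging its interior. Manual candling is slow and error-prone, which
motivates a machine-vision pipeline: photograph each egg in a dark box,
locate the egg in the frame, and classify the crop into one of three
classes — **unfertilized** (pale amber-yellow, translucent),
**live embryo** (dark red relative to the other classes, with black
blood vessels), or **abnormal** (a dead embryo showing dark foci or a
blackened mass, or a yolk-dispersed egg showing uniform yellow).

`eggcandler` implements that pipeline end to end in R: a synthetic
image generator that stands in for proprietary hatchery photographs, an
egg localisation chain, a 34-layer residual network with pluggable
attention modules, and a training/evaluation protocol that reports both
test metrics and training-stability statistics.

## Egg localisation

Captured frames place the egg in a small part of a large dark-box
image, together with a wall-reflection patch on the opposite side.
`preprocess_egg()` runs:

1. **Grayscale** conversion with BT.601 luma weights
   (0.299, 0.587, 0.114). The source imagery is broadband white-light
   transillumination, and these are the conventional weights; nothing
   downstream depends on the exact choice.
2. **Median filtering** (default 5×5, symmetric-reflection edges),
   which removes impulse noise while keeping the egg boundary sharp.
3. **Otsu thresholding with a manual offset.** Otsu's criterion picks
   the gray level `T` maximizing the between-class variance
   `w0 w1 (mu0 - mu1)^2`. On candling frames the adaptive optimum
   separates the dark box from *everything* bright — including the
   wall reflection (gray ≈ 180–200) and near-saturated shell light
   leakage (254–255). Raising the threshold by a manual offset
   (default +100, capped at 255) discards dim clutter while the
   transilluminated egg stays above threshold; foreground is "strictly
   greater than" the effective threshold. Ties in the Otsu scan are
   broken toward the smallest maximizing level, and a single-gray-level
   image raises a no-contrast error rather than returning an arbitrary
   threshold.
4. **Largest 8-connected component.** The reflection patch can survive
   thresholding; it is eliminated by keeping only the largest
   component (the generator guarantees the reflection is at most a
   quarter of the egg's area, so the selection is meaningful).
   8-connectivity tolerates one-pixel diagonal gaps from noise.
5. **1.1× bounding box and crop.** The component's tight box is scaled
   about its centre by 1.1 (then clamped), guarding against truncating
   the egg when the mask is slightly eroded at the rim; the crop is
   taken from the *original colour image* — the classifier needs the
   colour cues — and resized bilinearly to the model input size.

The input size defaults to 224×224, the conventional input for
residual networks of this family; it is configurable (any multiple
of 32) and the desk-scale experiments below use 96×96.

## The classifier

`build_classifier()` assembles the canonical 34-layer residual
network: a 7×7/stride-2 stem, stages of 3/4/6/3 basic blocks
(64/128/256/512 channels, scalable by `width_factor`), global average
pooling and a 3-way linear head. Each basic block computes
`y = ReLU(F(x) + Ws x)` where `F` is conv–BN–ReLU–conv–BN and `Ws` is
the identity, or a 1×1 strided projection when shapes change: with a
zeroed residual branch the block degenerates to a (projected) identity,
which is what lets deep stacks train without degradation. Batch
normalization follows each convolution, per the canonical design.

Attention is inserted *inside every block*, after the convolution
stack and before the shortcut addition:

* **Channel attention (CBAM part 1):**
  `Mc = sigmoid(MLP(AvgPool(F)) + MLP(MaxPool(F)))`, both pools over
  space, one shared two-layer MLP (reduction ratio 16 by default).
* **Spatial attention (CBAM part 2):**
  `Ms = sigmoid(conv7x7([AvgPool_c; MaxPool_c]))`, pools over
  channels, same-size padding (3).
* **SE:** global-average squeeze, two-layer excitation MLP (ratio 16).
* **CA (coordinate attention):** directional height/width average
  pools through a shared bottleneck (ratio 32) into separate
  per-height and per-width sigmoid gates. The published design uses a
  hard-swish bottleneck; this implementation uses ReLU, which does not
  change the gating structure.

All gates are sigmoid outputs in (0, 1) applied multiplicatively, so
attention can only attenuate: `|F''| <= |F|` element-wise, and zeroed
attention sub-networks give gates of exactly 0.5 (hence CBAM output
equal to a quarter of its input) — properties the test suite asserts
exactly.

The network, its backward pass and the Adam optimizer are implemented
directly on BLAS matrix operations (im2col/col2im in compiled code;
everything else is column arithmetic on an `(H*W*N) x C` layout).
Analytic gradients for every layer type are verified against central
finite differences in the test suite.

## Training and evaluation protocol

`candle_net()` performs a seeded stratified 6:2:2
train/validation/test split, normalizes channels with training-split
statistics, and trains with mini-batch Adam (defaults: 50 epochs,
batch size 16, learning rate 0.001, cross-entropy loss, random
horizontal flips). Every stochastic choice — split, shuffling,
augmentation, initialization — derives from the configured seed, so a
run is exactly reproducible from its config snapshot.

Interpretation notes on the augmentation list: "center cropping" is
the deterministic central-window step (a no-op when the crop already
matches the input size), and "dimensionality reduction" is the
resize-to-input-size already performed by preprocessing — no further
projection is applied. The evaluation path applies only deterministic
steps.

Two report types summarize a run:

* `stability_metrics()` reduces the per-epoch validation-accuracy
  sequence to its mean, overall population standard deviation and
  variance, and the population variances of the first and last 10
  epochs — the convergence/stability profile used to rank attention
  variants. Population (divide-by-N) variance is used throughout; the
  quantities are descriptive statistics of a fixed sequence, not
  sample estimates.
* `evaluate_model()` reports the aggregate confusion matrix (true
  classes in rows), accuracy and macro-averaged precision/recall/F1.
  Macro averaging weights the three classes equally, the conventional
  choice under moderate class imbalance. Because the evaluation path
  is deterministic, the "repeated test rounds" variance is produced by
  seeded bootstrap resampling of the test set (10 rounds by default)
  and the report is labelled `mode = "bootstrap"`; `resample = FALSE`
  yields identical rounds and zero variance.

`compare_attention_variants()` fits one model per attention module on
a single shared partition with shared seeds, pairing the comparison.

## The synthetic generator

No public candling-image archive exists, so `render_egg_image()`
draws images with the structure that matters to the pipeline: a dark
box background, one axis-aligned elliptical egg with a radial
brightness falloff mimicking transillumination, a wall-reflection
patch (gray 180–200, opposite side of the frame, area at most 16% of
the egg), shell light leakage at gray 254–255 along the rim of
unfertilized eggs, and per-class interiors: branching random-walk
vessels plus an embryo focus (live), dark foci / a blackened region /
uniform yellow for the abnormal subtypes. Gaussian noise and impulse
(salt-and-pepper) noise are applied last — the impulse noise exists
specifically to exercise the median filter. Everything is determined
by the seed, and each sample carries its ground-truth egg box for
testing the cropper.

Two palette decisions deserve explanation:

* **All interiors are bright.** The +100 offset means the effective
  threshold sits roughly 100 gray levels above the Otsu optimum, which
  in a well-separated scene lands at the top of the background
  cluster. Any egg whose rim luminance fell below that would be
  eroded or lost. The real scene behaves the same way — the egg is the
  *transilluminated* (bright) object — so the generator renders "dark
  red" as the darkest and reddest class (luminance ≈ 161–173) rather
  than photometrically dark, preserving the characteristic ordering
  live < abnormal(dead) < unfertilized.
* **Overlay features are near-background dark.** Vessels, embryo
  foci and blackened regions are rendered at luminance ≲ 30 so they
  merge with the background cluster in the histogram. Mid-gray
  features would drag the Otsu optimum upward and could push the
  effective threshold above the rim of live eggs. They also stay away
  from the rim, so holes in the thresholded mask never disconnect the
  egg component or shrink its bounding box.

Class palettes have pairwise-disjoint mean-luminance intervals
(`class_luminance_intervals()`), which is the separability knob: the
default dataset is linearly separable in colour statistics once the
egg is cropped. That is a deliberate property — it makes end-to-end
recovery a sharp test of the *pipeline* (localisation, plumbing,
optimization), not of the network's capacity. Passing it shows the
machinery works; it does not show the architecture's margin on real
eggs, where class evidence is subtler (uneven shell transmission,
intermediate colours, capture noise), nor does the generator model
shell texture, specular highlights, or multiple eggs per frame.

## Numerical and protocol choices

* Otsu tie-break: smallest maximizing level; the between-class
  variance curve is exactly flat across empty histogram gaps, so the
  rule is exercised in practice.
* Median-filter edges: symmetric reflection with edge duplication.
* Split rounding: per class, `round(n * 0.6)` train and
  `round(n * 0.8) - round(n * 0.6)` validation, remainder test —
  strata stay within one sample of the exact ratios and the partition
  is always exhaustive.
* Batch norm uses population batch statistics with running-statistic
  momentum 0.1 and eps 1e-5; evaluation uses running statistics.
* Weight init is seeded Kaiming-style for convolutions and the head;
  attention biases start at zero (so untrained gates sit at 0.5).
* Attention bottleneck widths are `max(2, C %/% ratio)` so reduced-
  width models keep a nonempty bottleneck.
* Degenerate inputs fail loudly: single-level images (no contrast),
  empty masks (no egg), empty classes in a split.

## Problem sizes used in the checks

The automated checks run at desk scale, chosen so the full suite
completes on one CPU in minutes: 100 synthetic images per class at
480×270 (one eighth of the 3840×2160 capture resolution) for the
localisation properties, and a width-factor-0.25 network at 96×96
inputs trained for at most 10 epochs (stopping early once validation
accuracy reaches 0.98) for end-to-end recovery over three seeds. The
full-width 224×224 configuration is exercised in the forward
direction. Training the canonical full-width model for the default 50
epochs is supported but is an hours-scale computation in this
implementation.

## Known limitations

* The generator's separable palettes make classification easy by
  construction; accuracy numbers on synthetic data say nothing
  quantitative about hatchery performance.
* No pretrained weights: networks train from scratch.
* Depth is fixed at 34 layers; bottleneck-block depths (50/101) are
  out of scope, as are off-the-shelf baseline architectures.
* Single egg per frame; no camera calibration or shell-texture model.
* CPU-only: wall-clock throughput is not comparable to a GPU
  deployment and no timing claims are made.
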