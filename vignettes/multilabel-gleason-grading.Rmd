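---
title: "Multi-label patch grading: model, label policy, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-label patch grading: model, label policy, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Patch-level Gleason grading datasets conventionally carry a single label per
patch: the grade occupying the most annotated pixels. Tissue is not that
tidy. A 512x512 patch routinely contains several Gleason patterns at once,
and under majority voting every pixel of a minority pattern is silently
mislabelled — on real prostate datasets the off-majority area averages
1-2% of a patch but reaches 30% in individual patches. A classifier trained
against such labels inherits that noise, and a patch carrying a small focus
of high-grade cancer is recorded as something else entirely.

`mlgleason` implements the multi-label alternative end to end:

1. **Audit** — quantify exactly how much pixel area majority voting
   mislabels, per grade and per dataset partition
   (`inconsistency_report()`).
2. **Relabel** — replace the majority vote with a threshold rule: every
   grade whose pixel fraction reaches a threshold $\tau$ enters the patch's
   label set; the non-cancerous (NC) label is issued only when *zero* grade
   pixels are present (`multilabel_from_mask()`).
3. **Detect** — train one binary CNN per grade (one-vs-all) and combine the
   three into an ensemble whose output is any subset of {G3, G4, G5}, with
   NC as the empty set (`train_ensemble()`, `predict_multilabel()`).
4. **Explain** — Grad-CAM heatmaps per sub-classifier and stitched
   whole-slide activation maps (`grad_cam()`, `slide_activation_map()`).

## The label policy

A grade $c$ enters the label set of a patch when

$$\mathrm{count}_c \ge \max(\texttt{min\_count},\ \lfloor \tau N \rfloor),$$

where $N$ is the pixel denominator. Defaults: $\tau = 0.01$ and
$N$ = all patch pixels, so for a 512x512 patch the gate is
$\lfloor 0.01 \cdot 262144 \rfloor = 2621$ pixels. One percent is low enough
to keep scarce high-grade examples in training and high enough that the
included pixels support a learnable feature. A tissue-pixel denominator is
available (`label_policy(denominator = "tissue_pixels")`) for datasets whose
patches carry large background margins; only the all-pixels choice
reproduces the 2621-pixel arithmetic above. `min_count = 1` guarantees
$\tau = 0$ never admits an absent class.

Two consequences of the joint NC/threshold rule deserve emphasis:

* **NC is strict.** A single grade pixel disqualifies NC, even though that
  pixel may be below every grade threshold.
* **A patch can be unlabelable.** If grade pixels exist but none reach the
  threshold, the label set is empty *and* NC is false. These
  sub-threshold-cancer patches are flagged `excluded`: they are kept out of
  sub-classifier training (they are exactly the label noise the method
  exists to remove) and reported separately at evaluation.

Majority-vote ties between grades break toward the higher grade — the
clinically conservative reading; the tie only matters for the audit, never
for the multi-label itself.

The audit defaults to the *present* population: mean and maximum
off-majority fraction are taken over the patches in which the class
actually occurs off-majority. Averaging over all patches instead
(`population = "all"`) answers a different question ("how much of the
average patch is mislabelled") and is provided as an option.

## The classifier

Each sub-classifier is a ResNet18 truncated to fight overfitting on small
histopathology datasets: the whole `conv5` stage and the second basic block
of `conv4` are removed, and global average pooling reads the ReLU output of
the first (projection-skip) `conv4` block directly:

| stage | layers | activation (224 input) |
|---|---|---|
| conv1 | 7x7/64 stride 2, BN, ReLU, 2x2 max-pool | 112x112x64, pooled 56 |
| block 2 | 2 x (3x3/64, BN), identity skip | 56x56x64 |
| block 3 | 2 x (3x3/128, BN), stride-2 entry, 1x1 projection | 28x28x128 |
| block 4 (half) | 3x3/256 + BN with 1x1 projection, block ReLU | 28x28x256 |
| head | GAP, FC, softmax | 256 -> 2 |

The stack is fully convolutional up to the pooling, so the same
architecture runs at any input side >= 16; `model_shapes()` prints the
propagated sizes. Because no deep-learning framework ships with this
package's environment, the network, its manual backpropagation, and Adam
are implemented in the package itself (C++ im2col/GEMM kernels, R layer
graph); the gradients are verified against central finite differences to
better than 1e-4 relative error in the test suite.

Training recipe (all defaults in `train_config()`):

* Adam, backbone learning rate 1e-3, dropped by 0.1 every 15 epochs;
  the fresh FC head always runs 10x faster than the (nominally pre-trained)
  backbone.
* Weighted cross-entropy with inverse-frequency weights
  $w_c = n/(2 n_c)$ — the "all" class of a one-vs-all split is inevitably
  the majority, and the weighting restores the minority's gradient share.
  The sample-weighted mean of these weights is 1, so the loss scale is
  untouched.
* L2 penalty 1e-2 on convolutional and FC weights only (not biases or BN
  parameters, the usual convention).
* Up to 50 epochs with early stopping after 8 consecutive epochs of
  strictly rising validation loss, measured against the immediately
  preceding epoch; the best-validation-loss weights are restored on stop.
* Augmentation on training batches only: resize to the network input,
  rotation uniform in +/-15 degrees, translation uniform in +/-10% of the
  side, horizontal/vertical flips with probability 0.5 each. Warped-in
  pixels are filled white, matching slide background. The magnitudes are
  package choices (mild, label-preserving transformations); they are
  exposed in `train_config()`.
* `init = "pretrained"` copies backbone weights from a user-supplied cached
  weight file; without one it errors and points at `init = "random"`, which
  every test and the acceptance pipeline use. BN layers always train.

Per-grade decision thresholds are *selected*, not fixed: each
sub-classifier's validation scores are swept into a precision-recall curve
(`pr_curve()`), and the threshold with maximal F1 (lowest such threshold on
ties) is stored in the ensemble. The sweep includes sentinels below the
minimum and above the maximum score so the curve always spans recall 1 down
to 0; at a threshold where no patch is predicted positive, precision is
defined as 0. Score comparisons are strict (`score > threshold`; ties
negative), which makes the decision rule monotone: raising a threshold can
only remove grades.

## Evaluation

Multi-label output has no single canonical "accuracy". The package reports,
over the non-excluded patches:

* per-class F1 for NC, G3, G4, G5, each as a binary presence/absence
  problem, and their arithmetic mean (macro F1) — the headline metric,
  appropriate under class imbalance;
* macro-averaged per-problem binary accuracy (the default "accuracy"); and
* subset accuracy (exact label-set match), the strictest reading.

Reference labels at evaluation may use their own pixel threshold
(`tau_test`), defaulting to the training $\tau$.

## The synthetic data generator

`generate_dataset()` exists so every stage — relabelling, training,
threshold selection, evaluation, explanation — can be exercised with no
external data. It emulates the *structure* of a pixel-annotated biopsy
patch dataset:

* white slide background; one contiguous tissue region with an H&E-like
  pink base and per-pixel Gaussian stain noise (tissue only, so empty
  windows stay exactly white and are degenerate for the tissue detector);
* grade regions as compact blobs (top-$k$ pixels of smoothed noise fields,
  so planted per-slide class fractions are exact by construction), painted
  with class-distinct colour and texture: G3 dark pink with sparse rings,
  G4 blue-purple with dense dots, G5 near-black solid sheets;
* pixel-aligned masks, patient-exclusive five-fold splits (shuffled
  round-robin, which balances class presence across folds because every
  slide carries the same mixture), square patches at 50% overlap, and an
  Otsu tissue filter at 20%.

The Otsu threshold is computed on Rec. 601 luminance over the 8-bit
histogram by exhaustive between-class-variance maximization; tissue is the
darker class. One numerical choice matters: the threshold is estimated once
per *slide* and applied per window. A window that is entirely tissue has no
background mode of its own, and a per-window threshold would split the
tissue itself, discarding exactly the high-grade interior patches the
dataset needs.

What the generator does *not* emulate: glandular morphology, stain
variability between slides or scanners, annotation disagreement between
pathologists, or any property a pathologist would recognise as tissue. A
model that separates these synthetic classes has demonstrated that the
pipeline — labelling, weighting, optimization, threshold selection,
stitching — is correct, not that it grades cancer; results on real slides
remain bounded by the usual domain gaps.

For the packaged validation runs the generator is scaled to desk size: 10
patients x 2 slides of 320x320 pixels, 64-pixel patches (about 1200 patches),
network input 48x48, 10 epochs from random init — roughly ten minutes on one
CPU core. At this scale the trained ensemble reaches macro F1 >= 0.9 on the
held-out patient fold with validation-selected thresholds; exact per-class
numbers for a given seed are produced by `scripts/acceptance.R`. Patch
fractions are planted exactly by `generate_patch_mask()` when an audit needs
bit-exact ground truth.

## Explanations

`grad_cam()` takes the gradient of the chosen (pre-softmax) logit with
respect to the last convolutional feature maps — the only conv output
feeding the head, the `res4a`-ReLU analogue, 28x28 for a 224 input —
averages it spatially per channel, forms the ReLU of the weighted channel
sum, upsamples bilinearly and normalizes to max 1. With a GAP + linear
head this gradient is constant per channel, so the closed form is exact and
is asserted in the tests. `slide_activation_map()` paints per-patch scalar
scores (or full Grad-CAM maps) onto slide coordinates, averaging overlaps
by coverage count; never-covered pixels are `NA`, not zero, so absence of
evidence is distinguishable from absence of activation.

## Known limitations

* The CNN engine is single-threaded CPU code built for correctness and
  desk-scale problems; full-scale training (224 input, thousands of
  patches, 50 epochs) is possible but slow, and no GPU path exists.
* ImageNet initialization requires a user-provided weight file; the package
  cannot fetch one.
* Patches and masks are PNG; JPEG input would need a reader dependency.
* No slide-level Gleason score aggregation (primary + secondary pattern) is
  attempted; the slide maps are qualitative.
* `load_patch_array()` holds the resized patch tensor in memory; at the
  packaged problem sizes this is a few hundred megabytes at most.
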