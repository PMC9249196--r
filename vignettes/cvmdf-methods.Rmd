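---
title: "Directional-filter CVM staging: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Directional-filter CVM staging: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvmdf)
```

## The problem

Cervical vertebral maturation (CVM) staging reads skeletal maturity off the
shapes of the C2–C4 vertebral bodies in a lateral cephalogram: as a patient
matures, notches deepen along the inferior borders and the C3/C4 bodies
progress from flat-bottomed trapezoids through horizontal rectangles and
squares to vertically elongated rectangles. The six-stage scheme (CS1–CS6)
merges into a five-stage scheme (CVMS I–V) by pooling CS1 and CS2, whose
distinction — a subtle C2 notch — is known to be unreliable. `cvmdf`
implements a fully automated staging pipeline: locate the vertebral column,
crop and normalize it, and classify the stage with a compact convolutional
network whose first layer is a bank of *directional edge filters* that is
initialized analytically and then fine-tuned by backpropagation.

## The directional filter bank

The 1-D prototype chain is exact dyadic-rational arithmetic throughout:

1. A 7th-order half-band Lagrange maximally flat lowpass,
   $H_{lp}(z) = 1 + \tfrac{9}{16}(z+z^{-1}) - \tfrac{1}{16}(z^3+z^{-3})$,
   with DC gain 2 and (by the half-band property) gain exactly 1 at
   $\omega = \pi/2$.
2. Modulation $H_{hp}(z) = H_{lp}(-z)$, giving taps
   $\{1, 0, -9, 16, -9, 0, 1\}/16$ and zero DC gain.
3. Smoothing by $h_c = \{1,2,1\}$ to suppress gain near $\omega = \pi$
   (noise amplification), yielding the 9-tap band-pass
   $h_{bp} = \{1, 2, -8, -2, 14, -2, -8, 2, 1\}/16$ with gain 2 at
   $\omega=\pi/2$ and 0 at $\omega \in \{0, \pi\}$.

```{r gains}
h_bp <- bandpass_prototype()
frequency_response(h_bp, c(0, pi / 2, pi))
```

One numerical note: the band-pass magnitude response is *not* maximized at
$\pi/2$ — direct evaluation shows a maximum of about 2.08 near
$\omega \approx 1.73$. The three gain anchors above are the design's
published characterization; the package asserts those, not a global-maximum
property.

The 2-D bank lays $h_{bp}$ along eight digital lines at
$\theta \in \{-63.43°, -45°, -26.56°, 0°, 26.56°, 45°, 63.43°, 90°\}$
(slopes $0, \pm\tfrac12, \pm1, \pm2, \infty$). Rather than rotating by
interpolation, taps are placed sparsely on the line; for the slope-$\pm$½
and slope-$\pm$2 lines, a tap whose ideal position falls halfway between two
cells is split equally between them, so the sums of coefficients along the
filter direction reproduce the 1-D taps *exactly* and every kernel keeps a
coefficient sum of exactly zero (no response to constant images; edges
produce zero-crossings). The $90°$ kernel is the transpose of the $0°$
kernel, and negative angles are mirror images. All coefficients are
multiples of $1/32$, exact in floating point, which is why the tests can
assert bit-exact identities.

Two kernel supports are provided: the default 9×9 realizes the full smoothed
band-pass; a 7×7 mode uses the 7-tap high-pass prototype instead, matching a
7×7 first-layer kernel budget while preserving the zero-DC property. The
choice is a config switch (`cnndf_config(directional_support = )`) and does
not change any downstream shape.

## The CNNDF classifier

`build_cnndf()` assembles the staging network for a 77×35 grayscale RoI:

* **Directional** conv layer, 8 filters initialized from the bank (flipped,
  so the layer's correlation equals the bank's convolution) — *trainable*;
* **Match**, a 7×7 depthwise conv initialized as a centered identity, so the
  initial forward pass is exactly directional filtering, followed by a leaky
  ReLU (slope 0.1);
* a parallel 1×1 conv + batch norm of the raw input, added back (the
  front-end residual);
* four blocks of 2×2/stride-2 max pooling (ceil mode — the only convention
  that yields the published 77→39→20→10→5 row progression) followed by a
  skip-connection block: 3×3 conv → batch norm → ReLU → dropout in parallel
  with a 1×1 conv → batch norm, summed; filter counts 32/64/128/256;
* a flatten (5·3·256 = 3840), Dense(64) → batch norm → ReLU, and a softmax
  output over 5 or 6 classes.

The default model totals 684,949 parameters (682,885 trainable plus
batch-norm running statistics), under the published 715 K budget.
`network_spec()` returns the layer table for auditing, and
`count_parameters()` the totals.

The directional and Match layers use symmetric (mirror) boundary padding so
that the zero-DC property holds up to the borders — a constant image
produces exactly zero pre-bias activation everywhere; the 3×3/1×1 block
convolutions use conventional zero padding.

**Training.** No deep-learning framework is involved: convolutions are
im2col gathers followed by BLAS matrix multiplications, and the
memory-bound steps (gather/scatter, the depthwise convolution, pooling,
layout permutes, fused batch-norm passes) run through small compiled
streaming kernels; the optimizer is minibatch Adam on categorical
cross-entropy. Correctness of every layer's gradient is enforced
by finite-difference checks in the test suite. The published design fixes
no optimizer, learning rate, batch size, epoch count or dropout rate; the
package defaults — Adam at $10^{-3}$, batch 32, 60 epochs, dropout 0.2 —
are conventional settings consistent with smooth convergence on this model
size, and all are exposed in `train_config()` / `cnndf_config()`. With a
fixed seed, initialization, shuffling and dropout are fully reproducible.
The ablation switch `cnndf_config(random_init = TRUE)` replaces only the
first layer's initialization with standard He draws (the with/without
directional-filter comparison apparatus); both variants consume the RNG
stream identically, so every other layer starts from identical weights.

Argmax ties at prediction break toward the lower class index — an arbitrary
but deterministic, testable convention.

## RoI detection

The vertebral column is localized by a compact channel-features detector:
8 channels (intensity, gradient magnitude, six unsigned orientation bins)
block-summed 4×4 and smoothed; a boosted ensemble (real AdaBoost) of 64
depth-2 trees scores a fixed window — sized from the median labeled box —
at every position of a $2^{1/4}$-step scale pyramid spanning half an octave
each way; greedy non-maximum suppression at IoU 0.5 keeps the best window.
Training draws random negatives (IoU < 0.3 with truth) plus two
hard-negative mining rounds over a capped image subsample at the central
pyramid scales — mining is the expensive step and the central scales supply
nearly all hard negatives. Everything is deterministic under
`roi_config(seed = )`. When no window clears the score threshold (the 2nd
percentile of training-positive scores), `detect_roi()` returns a zero-row
tibble — the explicit no-detection signal — and manifest crop columns take
precedence downstream, mirroring manual-crop fallback practice. This module
is deliberately a simplification of the classical aggregate-channel-features
detector (grayscale channels, one window aspect, shallow trees); it is
pipeline plumbing with a pluggable interface, not the scientific core.

## Preprocessing and augmentation

`crop_and_resize()` scales a crop by the *single* factor that fits it inside
77×35 (bilinear), then pads symmetrically with the crop's median intensity —
aspect ratio is never distorted, because relative vertebral proportions are
the signal being classified. `augment_image()` produces exactly ten
label-preserving variants: shifts of ±3 and ±6 px along each axis (eight)
and rotations of ±5° (two), median-filled. The counts and operation types
are fixed by the protocol (ten extra images per original, shifts plus
clockwise/counterclockwise rotations); the magnitudes are the package's
choice, kept small against the 35-px width. Median fill avoids injecting
high-contrast artificial edges that directional filters would amplify.
761 originals become 761 × 11 = 8371 images with class proportions exactly
preserved.

## Evaluation protocol

`make_folds()` builds a stratified 5-fold plan with largest-remainder
allocation (per-fold class counts within one image of exact proportion;
fold sizes differ by at most one — 761 images split 153/152/152/152/152).
The split happens *before* augmentation; `fold_split()` augments only the
training side, and every scoring entry point calls a lineage guard that
errors if an `is_augmented` row reaches evaluation. Reports carry the
confusion matrix (rows = truth), accuracy = trace/total, per-class
precision/recall/F1, and one-vs-rest ROC curves thresholded at every
observed probability with trapezoidal AUC; `average_reports()` averages
confusion matrices elementwise (fractional entries are expected) and
recomputes metrics from the average. The ROC/AUC implementation is
cross-checked against an independent library implementation in the tests,
and a random-score classifier comes out at AUC 0.5 ± 0.05 as it must.

**Subset significance.** The protocol splits a test set into 7
class-density-preserving subsets of 30 images and compares per-subset
accuracies with and without directional initialization. The published
procedure fits normal distributions to the two accuracy samples and reports
a p-value without naming the test; notably, the printed summary statistics
(means 0.778 vs 0.826, SDs 0.0762 vs 0.0633, n = 7) do **not** yield
p < 0.01 under standard two-sample tests (Welch's t on those moments gives
p ≈ 0.11). `subset_significance()` therefore computes and *reports* rather
than asserts: the default is a one-sided Welch test, with a
`"normal_overlap"` mode ($P(N(\mu_0,\sigma_0) \ge \mu_1)$) provided as the
closest reading of the fitted-normal description. Zero-variance edge cases
return 0.5 for identical samples and 0/1 for deterministic separation.

## The synthetic generator

Real cephalogram collections cannot be redistributed, so the package ships a
generator that emulates what the pipeline actually consumes: a 400×300
"radiograph" with smooth low-frequency background texture, a bright
elliptical skull-like distractor, Gaussian blur (σ = 1.2 px) and additive
noise (σ = 0.04), containing a stack of three bright vertebral bodies whose
geometry encodes the stage:

* notch (inferior-border concavity) on C2 only (CS2), C2+C3 (CS3), all
  three (CS4–6); depth grows from ~0.1 to up to 0.35 of body height, and
  "flat" means < 0.05;
* C3/C4 silhouette: trapezoid with superior/inferior width ratio 0.72–0.88
  (CS1–3); horizontally elongated rectangle, aspect 1.20–1.45 (CS4);
  near-square, 0.92–1.08 (CS5); vertically elongated, 0.68–0.84 (CS6).

The aspect windows operationalize the qualitative stage definitions around
the 1.15 / [0.9, 1.1] / 0.85 thresholds, with jitter on every parameter so
neighboring stages are close (the real task's dominant confusion mode). All
numeric morphometry is the generator's own — no measured anatomy stands
behind it. Each sample draws its own sub-seed from the master seed, so
generation is bit-reproducible and order-independent; the true RoI box
(stack bounds padded 10 %) accompanies every sample.

What passing tests on this generator do and do not show: they demonstrate
that the pipeline is correctly assembled and that the network can recover
stage-determining geometry from noisy renders (held-out accuracy ≥ 0.80
under the study-scale training run, RoI recall ≥ 0.90 at IoU 0.5); they say
nothing about accuracy on real radiographs, which involve anatomy,
projection and exposure variation the renderer does not model. The
published real-data figures (84.63 % / 75.11 % accuracy, 98 % detection)
are therefore out of scope for the test suite by design. Posture/tilt is
not simulated by default; `render_cephalogram(tilt_deg = )` shears the
column for users who want that confounder.

## Problem sizes used by the test suite

The suite runs the full published-scale *arithmetic* everywhere (761 → 8371
augmentation, 1018-row manifests, full-size network shapes), but trains at
study scale only where the property demands it: the stage-recovery check
trains on 1000 images (200 per merged class) for 30 epochs, and the
detector check trains on 300 images and scores 100 held-out radiographs.
Smaller fixtures (reduced widths, 15×9 inputs) drive the gradient checks
and toy-learning tests, because finite differences at full width would add
nothing but runtime.

## Known limitations

* No reference table of per-angle kernel coefficients was available to copy
  from; the kernels are reconstructed from the defining prototype equations
  and the sparse digital-line placement rule, and a different reconstruction
  could differ in the outermost taps. Every property the design states
  (zero DC, directional sums, transposes, gain anchors) is enforced exactly.
* The detector is a single-aspect, grayscale simplification; it is not a
  reimplementation of the reference detector.
* Training is CPU-bound R + BLAS; it is sized for the study-scale runs
  above, not for large-scale experimentation.
* PNG is the supported raster format for manifests.
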