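---
title: "Color-space ensemble UNet segmentation: model, data generator and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Color-space ensemble UNet segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

`segens` addresses binary semantic segmentation of crop foliage against a
field background (soil, weeds, debris) in top-down images, the perception
primitive an agricultural robot needs before it can act on individual
plants. Outdoor imagery makes this hard in a specific way: illumination and
soil appearance vary strongly, while the label definition ("this pixel is
crop") does not.

The package's model is an ensemble of k independent UNet classifiers
trained on *complementary color-space views* of the same annotated scenes.
With the default k = 2, member 1 sees the RGB image and member 2 the same
image converted to HSV. The views carry the same geometry and share one
annotation map, but they factor the signal differently: in HSV, hue is
largely invariant to the multiplicative brightness changes that dominate
outdoor variation, while value absorbs them; RGB preserves correlations
that HSV's nonlinearity distorts. Each member i produces a per-pixel crop
probability map $F_i(x) \in [0,1]$. A weight vector
$\omega = (\omega_1,\dots,\omega_k)$, $\omega_i \ge 0$, $\sum_i \omega_i = 1$,
defines both the training bookkeeping

$$ LO_j \;=\; \sum_{i=1}^{k} \omega_i \, LO_{ji} $$

(the weighted per-epoch loss over members, with binary cross-entropy as the
member loss) and the fusion rule at inference,

$$ F(x) \;=\; \sum_{i=1}^{k} \omega_i F_i(x), \qquad
   \hat y(x) \;=\; \mathbf 1 \{ F(x) \ge \alpha \}, $$

a pixel-wise convex combination followed by thresholding at
$\alpha \in (0,1)$ (default 0.5, ties classified as crop). Because the
members never share parameters and each trains only on its own view, this
is a bagging-style ensemble whose "subsets" are color-space views rather
than bootstrap samples (a bootstrap option exists but is off by default).

Fusion happens on probabilities, *before* thresholding. Thresholding each
member first and voting would discard exactly the calibrated disagreement
the ensemble is meant to exploit: a pixel where the RGB member says 0.45
and the HSV member says 0.75 is classified as crop by the fused rule, and
that is the intended behavior.

## The UNet members

Each member is a standard encoder–decoder UNet built by `build_unet()`:

* `depth` contracting stages of two 3×3 same-padded convolutions (ReLU)
  followed by 2×2 max pooling, feature channels doubling per stage;
* a double-convolution bottleneck;
* `depth` expanding stages of a 2×2 up-convolution (halving channels),
  concatenation with the matching encoder feature map, and two 3×3
  convolutions;
* a 1×1 convolution to one channel with sigmoid activation.

There is no fully connected layer. At `depth = 4` the walk over
`unet_layers()` enumerates 23 convolutional layers, the canonical
configuration. Parameter counts are a pure function of the descriptor
(`count_parameters()`), and a k-member ensemble carries exactly k times the
single-member count.

The network stack is implemented inside the package (forward pass,
backpropagation, Adam) with the convolution inner loops in C++ calling
BLAS `dgemm` on row-offset views of the feature arrays — a same-padding
3×3 convolution decomposes into nine shifted matrix products plus border
corrections, which avoids materializing im2col patch matrices. The
backward pass is verified against central finite differences in the test
suite, and the forward pass against a direct loop-nest convolution.

Numerical and design choices made where the design was genuinely open:

* **Padding.** Only same-padding is implemented, so predicted masks always
  match the input size and inputs must be divisible by `2^depth`. A
  valid-padding mode with center-cropped skip connections was considered
  and rejected: it shrinks outputs, complicating every downstream contract
  (mask alignment, metrics, file layout) for no benefit at these image
  sizes.
* **Output head.** One sigmoid channel paired with binary cross-entropy,
  not a two-channel softmax — the task is strictly binary.
* **No normalization layers.** The small networks used here (depth 2–4,
  base 2–16 channels) train stably without batch normalization, and
  omitting it keeps runs exactly reproducible at any batch size.
* **Initialization.** He fan-in scaling (`sd = sqrt(2/(k·k·c_in))`), zero
  biases, seeded.
* **Optimizer.** Adam (β₁ = 0.9, β₂ = 0.999, ε = 1e-8), default learning
  rate 1e-3, chosen once for the 64×64 desk-scale scenes on which the
  package's standing experiments run; minibatch size 8 by default.
* **BCE guard.** Predictions are clipped to `[1e-7, 1 − 1e-7]` inside the
  loss; gradients use the exact `(p − y)/N` form.
* **Max-pool ties** resolve to the earliest element in column-major order,
  keeping training bit-reproducible.

## Color spaces

All images are unit-range reals; 8-bit quantization happens only at file
I/O (`normalize_image()` divides raw 8-bit values by 255 on read). Hue is
stored as a turn fraction in `[0, 1)` — not degrees, and not the 0–179
8-bit dialect of common vision libraries — so that all three HSV channels
arrive at the network on the same `[0, 1]` scale as RGB. Hue of achromatic
pixels (saturation 0) is fixed at 0. The conversion is the exact hexcone
mapping: V equals the channel-wise maximum exactly, and the
`hsv_to_rgb(rgb_to_hsv(x))` round trip is the identity to below 1e-6.

## What the scene generator emulates — and what it does not

`generate_scene()` renders a top-down field scene from a `scene_spec()`:

* **soil**: smoothly mottled brown background (hue 0.05–0.11 turns by
  default) with spatial variation in hue, saturation and value, emulating
  changing soil texture and moisture;
* **crop**: `n_plants` rosettes of elliptical leaves in greens
  (hue 0.23–0.38), the ground-truth mask being exactly the union of leaf
  stencils;
* **weeds**: small green blobs rendered like vegetation but labeled
  background, reproducing the labeling convention in which only the crop
  class is foreground;
* **illumination**: a smooth multiplicative brightness ramp of strength
  `illumination_amplitude` (default 0.35) in a random direction — the
  mechanism that makes the RGB and HSV views informative about each other,
  since it moves V strongly while leaving hue nearly fixed;
* **sensor noise**: additive Gaussian noise (sd 0.02) after composition.

Defaults are fixed study conditions, not tuning knobs: 64×64 scenes, three
plants, two weeds. The generator is deterministic given its seed.

The generator does **not** emulate leaf occlusion geometry, specular
highlights, cast shadows with hard edges, plant growth stages, motion blur,
or any 3-D structure. Passing the package's tests therefore demonstrates
that the pipeline is correct and that fusion behaves as designed *under
these conditions*; it does not certify field performance on real crops,
where boundary ambiguity and annotation noise dominate.

`augment_pair()` implements the data-preparation convention that geometric
transforms (flips, quarter turns, continuous rotation ±30°, zoom 0.9–1.1,
translation ±10%) apply identically to image and annotation map —
nearest-neighbor resampling keeps the mask exactly binary — while pixel
transforms (Gaussian blur up to σ = 1, salt-and-pepper density 0.01) touch
the image only. The HSV view is derived from the *augmented* RGB image
rather than augmented independently, so the two views always depict
identical geometry; their pixel noise differs only through the conversion.
Regions mapped from outside the canvas become background (value 0, label
0) in both image and mask, so the synchrony is preserved at borders too.

`split_dataset()` assigns train/validation/test tags at 7:2:1 by default:
sizes are `floor(N·r/sum(r))` with the remainder joining the training set
(4000 items split exactly 2800/800/400). The default splits at item level
*after* augmentation, matching the stated pipeline order; because
augmented copies of one base scene are near-duplicates, this leaks
appearance information across splits, so a `by = "scene"` option keeps all
copies of a base scene inside one split (with approximate subset sizes,
whole scenes being indivisible). The standing benchmark uses the item-level
split deliberately, to mirror the pipeline it models.

## Training bookkeeping

`train_ensemble()` trains each member for `epochs` passes with Adam and
records, per epoch j and member i, the training loss `LO_ji` and the
validation pixel accuracy `AC_ji` (accuracy is evaluated on the validation
split at epoch end; with no validation items it falls back to the training
collection). The history stores `LO_j = Σ ω_i LO_ji` exactly as
accumulated, the member matrices, and the end-of-run averages `LO/n` and
`AC/n`. Note that `AC_j` accumulates member accuracies *unweighted*, per
the ensemble bookkeeping convention, so it ranges up to k rather than 1; a
mean member accuracy is provided alongside. Every member is initialized
and shuffled from the same seed, which has two useful consequences: runs
are reproducible end to end, and jointly permuting members and weights
leaves the recorded history invariant.

## The standing experiment

`benchmark_ensemble()` is the package's own test of the claim that fusing
color spaces retains the advantages of each. Per seed it renders 30 base
scenes, augments to 400 items, splits 7:2:1, trains both members for 8
epochs (the task converges by roughly epoch 6 at these scales), and scores
the test split three ways: each member alone and the fused map. Problem
sizes — 64×64 pixels, depth 3, 8 base channels, 8 epochs, 3 seeds — were
chosen once as the smallest configuration on which single members reliably
exceed 0.8 IoU, so that fusion effects are visible above noise. The
acceptance check asserts the desk-scale analogue of the ensemble claim:
mean fused test IoU over seeds 1–3 is no more than 0.01 below the mean of
the two single-view IoUs, and clears 0.6 absolute. In the measured runs the
fused IoU in fact exceeds both single views in every seed.

## Known limitations

* Double-precision CPU training only; no GPU path. The implementation is
  sized for method study and desk-scale experiments, not for production
  training runs.
* Only RGB and HSV views are built in; the view mechanism is a named list,
  so further color spaces can be added, but conversions beyond the pair are
  out of scope.
* The fusion rule is weighted averaging; a trained meta-combiner (stacked
  generalization in the strict sense) is not implemented, though
  `fuse_predictions()` is the single seam where one would go.
* IoU is reported for the crop class only (with the both-empty convention
  IoU = 1), as the mean of per-image IoUs; a pooled global IoU is also
  computed in evaluation reports.
* JPEG input requires the optional `jpeg` package; the native format is
  8-bit PNG, and 16-bit input is rejected rather than rescaled.
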