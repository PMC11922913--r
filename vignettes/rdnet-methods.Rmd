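---
title: "Methods: multi-fusion enhancement and the residual depth-wise classifier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-fusion enhancement and the residual depth-wise classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdnet)
```

`rdnet` implements a complete benign/malignant mammogram classification
pipeline: classical contrast-enhancement operators, a compact residual
depth-wise convolutional network with its own training loop, a
split-and-evaluate protocol, and a synthetic phantom generator that makes the
whole pipeline testable without clinical images. This vignette records the
models, the tunable parameters, and the design decisions taken where
conventions genuinely vary, so that every numeric behavior of the package is
accounted for.

## 1. Contrast enhancement

Mammograms concentrate most of their dynamic range in a narrow intensity
band; the enhancement module spreads that band out before classification.
All operators act on `gray_image` objects — integer matrices with `L`
representable levels (256 by default) — and all arithmetic is exact and
unit-tested against independent brute-force evaluations.

### Histogram equalization

For an `n × m` image with histogram `H(k)`, the normalized frequencies are
`N(k) = H(k)/(n·m)`, the cumulative distribution is
`CDF(j) = Σ_{k ≤ j} N(k)`, and each pixel is remapped through
`P = round((L−1)·CDF(x))`.

Two numerical choices matter:

* **Rounding.** Halves round *up* (`floor(x + 0.5)`), applied identically
  everywhere a look-up table is built. R's own `round()` rounds half to even,
  which would make tables disagree with a direct evaluation of the formula at
  exact halves.
* **CDF accumulation.** The CDF is computed as `cumsum(counts)/total`, not
  `cumsum(counts/total)`: cumulating the integer counts first avoids
  floating-point drift that can flip a value sitting exactly on a rounding
  half-way point. This is what makes the "CLAHE with one tile equals global
  equalization" reduction hold bit for bit rather than merely approximately.

### CLAHE

Contrast-limited adaptive histogram equalization applies the same idea per
tile, with a ceiling on how much any intensity can be amplified:

1. the image is partitioned into a `tile_grid` (default 8 × 8) of contiguous,
   near-equal tiles;
2. each tile's histogram is clipped at `C = clip_factor × tile_pixels / L`
   (default `clip_factor = 2`, i.e. twice the mean bin height — the common
   convention);
3. the clipped excess is redistributed evenly over all bins; because the
   arithmetic is kept integral (the effective ceiling is
   `max(1, floor(C))`, capped at the tile pixel count), the integer remainder
   is handed out one unit per bin starting at bin 0, and tile mass is
   conserved *exactly*;
4. each tile's equalization map is built from the clipped cumulative
   histogram;
5. every pixel is mapped by bilinear interpolation between the maps of the
   four nearest tile centers; border pixels clamp to the available two or
   one. An `interpolation = "none"` mode maps each pixel through its own
   tile only — it exists so tests can compare against an independent
   per-tile reference, not for production use.

Redistribution is single-pass: bins just below the ceiling may end slightly
above it after receiving their share. Iterating redistribution to a fixed
point changes results negligibly and costs determinism in the remainder
hand-out, so the package deliberately does not.

### Inversion and high-boost sharpening

Inversion is `I'(x, y) = (L−1) − I(x, y)`, an involution useful for viewing
dark structure on bright backgrounds. High-boost sharpening is computed in
real arithmetic as `A·f − LowPass(f)` (equivalently
`(A−1)·f + HighPass(f)`; the two forms agree to machine precision before
quantization) and clipped to `[0, L−1]` and rounded **once, at the end** —
never per intermediate step.

The low-pass filter is a separable Gaussian, truncated at three standard
deviations and normalized to unit mass, with *reflected* (edge-repeating)
boundary samples. With a symmetric kernel this extension makes the operator
doubly stochastic, so a constant image is a fixed point and the image mean is
preserved — both properties are asserted in the tests.

### Fusion recipes

`fusion_config()` composes steps left to right. The default recipe is CLAHE
followed by high-boost (`A = 1.5`, `σ = 1`): local contrast stretching first,
then edge amplification of the stretched image. Inversion is available as an
optional step. The choice of this particular order is a package default, not
a law; practitioners combine these operators in several orders, and the CLI
(`--steps`) and API make the recipe fully configurable. Color inputs are
collapsed to Rec. 601 luminance before enhancement, and the enhanced single
channel is replicated to three channels for the network.

## 2. The residual depth-wise network

The classifier factorizes convolution into a per-channel *depth-wise* 3 × 3
spatial kernel followed by a 1 × 1 *point-wise* cross-channel mix. A
depth-wise stage over `C` channels costs `9C + C` parameters against
`9C² + C` for a standard convolution — the parameter saving that motivates
the architecture. The default layer graph (input 128 × 128 × 3, widths
32 → 64) is:

```{r}
print(build_rdn(rdn_config(), seed = 1))
```

Decisions where reasonable conventions differ, and what this package does:

* **Padding.** `same` padding end to end, so spatial size is preserved
  through the convolutional trunk. A `valid` mode exists (each 3 × 3 kernel
  shrinks a side by 2, e.g. 128 → 126) and is exercised by the shape
  propagator's tests, but `valid` cannot be used in the residual block — the
  two addition operands would have different spatial sizes, and construction
  fails with an error naming both shapes.
* **Pooling.** None in the default network; the trunk feeds the flatten
  layer at full resolution (128·128·64 = 1,048,576 features into the dense
  head — deliberately literal, not replaced by global pooling). A 2 × 2
  max-pool layer type exists for shape propagation (126 → 63) and forward
  use.
* **Head.** A single dense unit with a sigmoid: the output is
  `P(malignant)`. A two-unit softmax is the same model with more parameters.
* **Batch normalization** follows each depth-wise convolution, before its
  ReLU; the 1 × 1 convolutions carry plain ReLU (none on the block output
  and shortcut, which are summed raw, as is conventional for projected
  residuals).
* **Dropout** (rate 0.5 by default) sits before flatten, implemented as
  inverted dropout: surviving units are scaled by `1/(1−rate)` so
  expectations match between train and inference mode. `dropout_mask()`
  exposes the exact mask primitive the layer uses.
* **Initialization.** Seeded He-style draws (`sd = √(2/fan_in)`) for ReLU
  layers and `√(1/fan_in)` for the sigmoid head; biases start at zero.

Internals: activations are `(H, W, C, N)` arrays; spatial convolutions go
through im2col + BLAS GEMM, depth-wise convolutions through a nine-term
shift-and-add, and every backward pass is verified against central finite
differences to 1e−4 relative error in the test suite. All convolutions are
stride 1, which keeps the input gradient an exact full convolution with the
spatially flipped kernel.

## 3. Training and evaluation protocol

* **Split.** 80/10/10 train/validation/test. Partition sizes are
  `round(fraction × n)` for validation and test with the remainder assigned
  to training; stratified mode (default) applies the rule per class, so each
  partition preserves the class ratio to within one image. A class smaller
  than the number of partitions degrades to an unstratified split with a
  warning. Splits are seeded and reproducible.
* **Preprocessing.** Bilinear resize to the network's input size, grayscale
  replicated to three channels, 8-bit intensities divided by 255. Inputs
  already normalized and already sized pass through unchanged, making the
  operation idempotent.
* **Positive class and threshold.** Malignant = 1 is the positive class —
  recall is malignant sensitivity, the clinically critical number.
  Probabilities `≥ 0.5` are called malignant (ties positive).
* **Loss and optimizer.** Binary cross-entropy minimized by Adam
  (lr 1e−3, β₁ = 0.9, β₂ = 0.999) in mini-batches of 32 for 10 epochs by
  default. These are plumbing defaults for desk-scale experiments, not tuned
  clinical settings. Non-finite loss aborts with a divergence diagnostic.
* **Augmentation** (off by default): horizontal flip with probability 0.5
  and rotation uniform in ±10°, both label-preserving for breast imagery and
  seeded. Class imbalance handling — inverse-frequency loss weights or
  per-epoch majority undersampling — is available but off by default.
* **Metrics.** Accuracy, precision, recall, specificity, F1 from the
  confusion counts, as fractions; any zero denominator yields `NA`, an
  explicit "undefined" marker, never a silent zero or an exception.
  Percentages are a presentation concern only.

All training randomness (shuffling, dropout, augmentation, undersampling)
flows from the single `train_config()` seed: two runs with equal seeds
produce bitwise-identical weights and histories.

## 4. Synthetic phantoms

`generate_phantom()` emulates what a screening mammogram is *for this
pipeline*: a bright elliptical breast region on a dark background, filled
with smoothed-Gaussian-noise fibroglandular texture, containing one bright
lesion. The class signal is boundary morphology:

* benign — radially smooth blob: boundary radius `r(θ) = r`;
* malignant — spiculated star: `r(θ) = r(1 + irregularity·cos(kθ + φ))`
  with `k` spicules drawn from `spicule_count_range`.

Both classes draw the base radius `r` from the same range (12–20 px at the
default 128-px image), so lesion *size* carries no signal. Each phantom
records ground truth: center, radius, spicule count, and a boundary
roughness score (radial standard deviation over mean — analytically
`irregularity/√2` for the star, 0 for the blob). This gives the pipeline a
known-learnable dial: at `irregularity = 0` the roughness score separates
the classes at chance (AUC ≈ 0.5 over 200 samples), while at the default
0.35 it separates them almost perfectly (AUC > 0.9) — both ends are
asserted in the tests, and the second is what makes the training smoke test
meaningful. The `imbalance = "paper"` preset reproduces the strong
benign-majority ratio (6,200:1,005) typical of screening archives, scaled to
the requested total.

Defaults (texture scale 8 px, additive noise σ = 8 levels, lesion contrast
70 levels) were chosen once as a plausibly difficult but learnable regime
and are not tuned to any test. What phantoms deliberately do **not** model:
anatomy (pectoral muscle, skin line, vessels), CC/MLO view geometry,
calcification clusters, acquisition physics, or JPEG artifacts (fixtures are
PNG precisely to avoid compression nondeterminism). Passing tests therefore
demonstrate that the pipeline is correct and can learn a morphology signal —
not that it reaches any particular accuracy on clinical mammograms.

## 5. Problem sizes used by the tests and acceptance script

Exact-arithmetic checks run on small images (≤ 16 × 16) where brute-force
oracles are exhaustive or near-exhaustive. The learning smoke test trains a
scaled network (input 32 px, widths 16 → 32, dropout 0.25) on 200
default-size phantoms for 10 epochs across three seeds, requiring ≥ 90%
training accuracy on at least two — sized so the full suite runs in a few
minutes on one CPU while still exercising every layer type's forward and
backward pass. The acceptance script re-runs one such training from scratch
and additionally estimates the dropout zero-fraction from 100,000 masks of a
100-unit layer (reported against the 0.5 default rate).

## 6. Known limitations

* No DICOM ingestion (clinical archives export JPG/PNG here; medical-grade
  pipelines should decode DICOM with proper windowing).
* No multi-scale/wavelet enhancement; the fusion steps are single-scale.
* The trainer is CPU-only base R: practical for desk-scale experiments and
  the 128-px architecture at small n, not for training on thousands of
  images.
* No cross-validation, hyperparameter search, ROC analysis, or calibration;
  the evaluation module reports threshold metrics only.
* Phantom realism is intentionally limited (see §4); conclusions about
  clinical performance require clinical data.
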