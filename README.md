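# rdnet

Benign/malignant mammogram classification in pure R: multi-fusion contrast
enhancement, a compact residual depth-wise convolutional network trained
in-package, a seeded preprocessing/split/evaluation protocol, and a synthetic
phantom generator so the entire pipeline can be developed and tested without
clinical data.

## The problem

Screening mammograms are low-contrast X-ray images in which early malignant
lesions are subtle: dense fibroglandular tissue obscures masses, and the
visual difference between a harmless cyst and a cancer is often a matter of
boundary morphology (smooth and round versus irregular and spiculated).
`rdnet` packages two ingredients of a computer-aided diagnosis workflow:

1. **Multi-fusion enhancement.** Classical intensity operators that make
   lesion structure easier to learn from, implemented from scratch with exact,
   testable arithmetic:
   - *Histogram equalization* (HE): remap each pixel through the image's
     cumulative distribution, `P = round((L-1) · CDF(x))` for an `L`-level
     image.
   - *CLAHE* (contrast-limited adaptive HE): per-tile equalization with each
     tile histogram clipped at `clip_factor ×` the mean bin height, the
     clipped mass redistributed evenly, and per-pixel bilinear interpolation
     between the four nearest tile maps.
   - *Inversion*: `I'(x,y) = 255 − I(x,y)`.
   - *High-boost sharpening*: `A·f − LowPass(f)` with a separable Gaussian
     low-pass filter (reflected boundaries), equivalently
     `(A−1)·f + HighPass(f)`.
2. **A residual depth-wise network (RDN).** A small CNN that factorizes
   convolutions into per-channel (depth-wise) 3×3 kernels followed by 1×1
   point-wise channel mixing, with a 1×1-projected additive shortcut — far
   fewer parameters than standard convolutions of the same width. The head is
   a sigmoid unit giving `P(malignant)`; training minimizes binary
   cross-entropy with Adam. Forward and backward passes are implemented in
   base R on top of BLAS matrix products.

Evaluation uses the standard confusion-matrix metrics — accuracy, precision,
recall (sensitivity), specificity and F1 — with malignant as the positive
class and an explicit "undefined" marker for zero-denominator cases.

## Worked example

Generate 200 synthetic phantoms (benign = smooth bright blob, malignant =
spiculated star), fit the classifier, and inspect the result:

```r
library(rdnet)

ds <- generate_dataset(phantom_config(n_benign = 100, n_malignant = 100, seed = 11))

fit <- rdn_fit(ds,
               net_config = rdn_config(input_size = 32, block_widths = c(16L, 32L),
                                       dropout_rate = 0.25),
               train = train_config(epochs = 15, batch_size = 32, seed = 1),
               seed = 1)
print(fit)
#> Residual depth-wise network fit
#>   parameters: 35937   split (train/val/test): 160/20/20
#>   final epoch 15: loss 0.0218, accuracy 1.000, val accuracy 1.000
#>   test accuracy: 0.950
```

The printed numbers mean: the 35,937-parameter network was trained on 160
images and by epoch 15 classifies every training and validation image and 19
of the 20 held-out test images correctly — the phantom classes are separable
by boundary morphology, and the network finds that signal. `predict(fit, ds)`
returns per-image malignancy probabilities, `plot(fit)` draws the loss and
accuracy curves, and `summary(fit)` prints the test-set confusion matrix and
the five metrics.

Enhancement is available standalone or fused:

```r
img <- ds$images[[1]]
enhanced <- apply_fusion(img, fusion_config())   # CLAHE then high-boost
```

## Command line

An installed `exec/rdnet` script (see `system.file("exec", "rdnet", package =
"rdnet")`) exposes the workflow as subcommands:

```sh
rdnet synth   --n-benign 100 --n-malignant 100 --seed 1 --out data/
rdnet enhance --in data/benign --out enhanced/ --steps clahe,highboost
rdnet train   --data data/ --out run/ --epochs 10 --input-size 32 --widths 16,32
rdnet evaluate --model run/model.rds --data data/ --out run/
rdnet predict  --model run/model.rds --image data/malignant/phantom_0101.png
```

Every run writes a `resolved_config.json` snapshot next to its outputs.

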