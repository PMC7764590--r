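---
title: "Two-stage segmentation of liver-scaffold whole-slide images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage segmentation of liver-scaffold whole-slide images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scaffseg)
```

## The problem

Decellularized liver scaffolds are evaluated from H&E-stained whole-slide
scans (WSS): gigapixel pyramidal images of entire tissue sections.  The
first step of any downstream texture analysis is a semantic segmentation of
every pixel into three classes — slide **background**, **intralobular**
tissue (the fine sinusoidal-vessel network inside a lobule) and
**extralobular** tissue (the interlobular septa of thick protein fibers).
Fully annotated training data do not exist at this scale; what an operator
can realistically provide is a handful of colored polygons per slide
marking unambiguous examples of each class.

`scaffseg` therefore works in two stages:

1. **HCTFS** (hand-crafted texture feature segmentation): a Gaussian naive
   Bayes (GNB) classifier over a nine-channel per-pixel texture descriptor,
   pretrained on the pooled polygon annotations of a training set and
   fine-tuned on each slide's own partial annotation before use.
2. **UNet-Mini**: a miniature encoder–decoder CNN trained on the stage-1
   output as pseudo-labels.  Once trained it segments new slides with no
   per-image annotation at all, and smooths over stage-1's occasional
   mislabels.

## Working resolution and annotations

Slides are processed at a working resolution of 10 µm per pixel, obtained
from the finest pyramid level at or below the target and resampled
bilinearly.  A scan 44,054 px wide at 227 nm per pixel becomes a
1000 px-wide working bitmap.  Annotation polygons are stored in base-level
pixel coordinates and rescaled into the working frame by multiplying each
vertex by the pixel-size ratio.

Polygon colors carry the class semantics: magenta = background, black =
intralobular, red = extralobular.  Green, cyan, blue and yellow mark
auxiliary delineations (typically the central vein); they are parsed and
round-tripped but never contribute training labels.  Unknown colors are
demoted to auxiliary with a warning rather than guessed.

Rasterization uses even-odd point-in-polygon tests at pixel centers
(0-based integer + 0.5).  Overlapping polygons of different classes are
resolved by drawing order — later polygons overwrite earlier ones — which
is this package's choice; the annotation workflow it models does not
specify one.

## The stage-1 feature bank

Nine features per pixel, computed on intensities scaled to [0, 1]:

| # | feature | parameters |
|---|---------|------------|
| 1–3 | raw R, G, B | — |
| 4–5 | Gaussian smoothing of R | σ = 2, 5 px |
| 6 | Sobel gradient magnitude of R | √(gx² + gy²) |
| 7–8 | Gaussian smoothing of the Sobel response | σ = 2, 5 px |
| 9 | median of the Sobel response | disk, 10 px diameter |

Only the red channel feeds the filter bank; in H&E material it is strongly
correlated with the other channels, so the extra filters add texture
information rather than redundant color.  Numerical conventions that the
tests pin down: Gaussian kernels are truncated at 4σ and normalized;
boundaries are handled by mirror reflection; the Sobel response is the
unsigned gradient magnitude; the median disk has radius 5 (center
included, 81 samples, always an odd count).  The intensity scale of the
features is fixed at [0, 1].

## The GNB classifier and per-slide fine-tuning

The model stores per-class, per-feature sufficient statistics (count, sum,
sum of squares) rather than finished moments, so *pretraining* on a corpus
of slides and *fine-tuning* on a target slide's partial annotation are the
same operation: accumulation.  Fine-tuning augments the pretrained
statistics instead of replacing them; the resulting moments are identical
to a pooled fit on all data ever seen (tested to 1e−9).  Class priors
default to observed label frequencies.

A variance floor of 1e−9 (on the [0, 1] intensity scale) guards against
degenerate classes: a partial annotation can easily cover a region where
one feature is constant.

Prediction evaluates, per pixel, the naive-Bayes log-score
log π<sub>c</sub> + Σ<sub>i</sub> [ −½ log(2π σ²<sub>ci</sub>) −
(x<sub>i</sub> − μ<sub>ci</sub>)² / (2σ²<sub>ci</sub>) ],
normalizes the exponentials into posteriors, and takes the argmax with
ties resolved to the lowest class code for determinism.

Whole-slide prediction runs in 255 px tiles with a 32 px halo — larger
than any filter support (the widest is the σ = 5 Gaussian truncated at
4σ = 20 px applied to the 1 px-support Sobel response) — so the stitched
result is pixel-identical to processing the slide in one piece, which the
test suite asserts.

## The stage-2 dataset

Stage-1 segmentations of the training slides become pseudo-labels.  Scans
are converted to grayscale (Rec. 601 luminance 0.299 R + 0.587 G +
0.114 B), then cut into 224 × 224 crops with 100 px overlap (stride 124)
at full, half and quarter resolution — any scale whose smaller side falls
below 224 is skipped — plus one whole-scan resize to 224 × 224.  Images
are resampled bilinearly, labels by nearest neighbour.

Augmentation produces three modified copies per crop (originals are kept,
so the dataset grows exactly fourfold: 11,384 crops become 45,536
records).  Each copy applies a random subset of horizontal flip, vertical
flip, additive white noise and Gaussian blur; every operation is included
independently with probability 0.5 and an empty draw is repeated.  The
magnitudes are this package's choice, as the procedure it implements
leaves them open: noise σ = 0.02 on the [0, 1] scale and blur
σ ~ U(0.5, 1.5) px — strong enough to matter, weak enough to keep the
pseudo-labels valid.  Flips transform image and label together; noise and
blur touch only the image.  Splits are assigned per scan (25/4/4 in the
full design), never per crop, so no scan leaks across subsets.

## UNet-Mini

The network is deliberately small — 123,219 trainable parameters against
the ~17 M of a classical U-Net — because the pseudo-labeled dataset is
small and a large decoder would simply memorize stage-1's mistakes.

* Encoder: four stages of conv 3×3 (stride 1, zero padding) → batch norm →
  ReLU → max-pool 2×2, with 16, 32, 64, 64 kernels.
* Decoder: four stages of ×2 nearest upsampling → conv 3×3 → **additive**
  skip connection from the matching encoder scale → batch norm → ReLU,
  with 64, 32, 16, 16 kernels.
* Head: conv 1×1 to 3 maps, per-pixel softmax.

Design choices that the architecture description leaves open, fixed here
and verified by the parameter-count test: decoder widths are (64, 32, 16,
16) — the mirror reading (64, 64, 32, 16) would give ≈158 k parameters,
contradicting the stated ~128 k budget, so the printed budget is treated
as binding.  Skip taps are taken post-ReLU/pre-pool; where the encoder is
wider than the decoder only the leading decoder-width channels are added,
keeping the skips parameter-free.  Downsampling is 2×2 max-pooling (the
convolutions themselves are stride 1).  Batch-norm uses ε = 1e−5 and
running-average momentum 0.1; inference uses the running statistics.

Training minimizes pixel-wise cross-entropy with label code 0 (padding)
excluded from both loss and gradient — the suite verifies exact additivity
of the masked loss over disjoint valid-pixel sets.  Optimizers: Adam with
standard parameters (lr 1e−3, β = 0.9/0.999, ε = 1e−8) or plain SGD
starting at lr 0.01 with step decay ×0.1 every 10 epochs; the reference
schedule is 35 epochs at batch size 32.  The backward pass is implemented
from first principles (im2col + BLAS GEMM convolutions, batch-coupled BN
backward) and is checked against central finite differences to 1e−4.

Whole-slide inference tiles the scan 224 × 224 with 100 px overlap and
averages the probability maps in the overlaps before the argmax.  Inputs
not divisible by 16 are edge-padded and cropped back.

## The synthetic study

Because the original 33-slide corpus is not distributable, the package
ships a simulator that generates slide-like scans with exact ground
truth: a rounded tissue region containing a Voronoi tessellation of
lobules (default 24 seeds in a 768 × 768 scan at 10 µm/px), septa of
~10 px along the Voronoi boundaries with oriented fiber striping, pale
intralobular interiors with scattered darker elliptical dots, and a
near-white background.  Class mean luminance is ordered background >
intralobular > extralobular, and the generator asserts this post-hoc
rather than assuming it.  Partial annotations are small convex polygons
placed strictly inside single-class regions (≤5 % total cover, three per
class by default), so annotation purity is exact by construction.

What the simulator does *not* model: stain variability, scanner noise and
compression, out-of-focus regions, tissue folds, and the long-tailed
texture statistics of real scaffolds.  Passing the end-to-end tests
therefore demonstrates that the pipeline's mechanics are correct and that
it can learn separable-but-noisy textures — not that the accuracy figures
transfer to real slides.

The end-to-end test uses 6 scans (4 train / 1 dev / 1 test) at 768 × 768
and a reduced CNN schedule of 10 Adam epochs without augmentation; these
problem sizes are the package's desk-scale profile, chosen so the whole
suite runs on one CPU core in minutes while still exercising every stage
at whole-slide geometry.  Both stages are required to reach 0.85 pixel
accuracy against ground truth; in practice stage 1 lands around 0.9 and
the CNN at or above it.

## Evaluation

`pixel_accuracy()` implements the recognition rate: the fraction of
evaluated pixels whose predicted class matches the reference, with
reference code 0 excluded.  Slides are evaluated stitched, not per crop.
The per-class weighting question does not arise — the metric is the plain
overall accuracy — but per-class recall is reported alongside the 3×3
confusion matrix for diagnostics.  `compare_methods()` reports both
stages' accuracies and their difference, the quantity of interest when
checking that distillation did not degrade (and typically improves on)
its teacher.

## Known limitations

* The NDPI/NDPA vendor formats are supported only through conversion into
  the package's TIFF + JSON schema; native readers are out of scope.
* Label masks are written as 8-bit grayscale PNGs carrying raw codes 0–3
  rather than palette-indexed PNGs (the palette encoding is not available
  in the underlying writer); semantics are unchanged.
* The CNN trains on the CPU; a 35-epoch full-scale run is feasible but
  slow, and the desk-scale profile above is the tested configuration.
* Checkpoints store weights and running statistics but not optimizer
  state; resuming training restarts the optimizer.
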