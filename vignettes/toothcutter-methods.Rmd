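---
title: "Methods: bitewing segmentation and per-finding classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bitewing segmentation and per-finding classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(toothcutter)
```

## The problem

A bitewing film captures the crowns of the upper and lower posterior
teeth in one frame. Reading it for interproximal caries and for
restorations is routine, repetitive and examiner-dependent, which makes
it a natural target for automation. `toothcutter` implements a complete
desk-scale pipeline for this task: the film is binarized, cut into
single-tooth half images, assembled into balanced per-finding
databases, and judged by one convolutional network per finding. A
synthetic bitewing generator with exhaustive ground truth stands in for
clinical data, so every stage is testable end to end.

## Preprocessing: frequency-domain sharpening and Otsu binarization

A bitewing decomposes into three intensity bands: background (close
to 0), alveolar bone (intermediate), and tooth crowns (above 120 on an
8-bit scale). Direct thresholding is unreliable because the bands are
uneven across the film, so the image is first sharpened in the
frequency domain. The Gaussian high-pass transfer function

$$H(u,v) = 1 - \exp\!\left(-\frac{D(u,v)^2}{2 D_0^2}\right)$$

(with $D$ the distance from the spectrum center and $D_0$ the cutoff
frequency) extracts edges and small impurities; subtracting the
filtered image from the original removes them while preserving the
broad bands, and Otsu's method — the exhaustive sweep over all 255
histogram splits maximizing between-class variance — then separates
foreground (teeth and bone, set to 255) from background (set to 0).

Numerical choices, all configurable:

* **Cutoff frequency** `cutoff = 30` by default, suited to films a few
  hundred pixels across; smaller values pass more non-edge content,
  larger values lose edge completeness.
* **Denominator form.** The standard Gaussian high-pass divides by
  $2 D_0^2$; a variant dividing by $2 D_0$ (dimensionally anomalous,
  occasionally seen in print) is available as
  `denominator = "as_printed"` for comparison.
* **Ideal high-pass orientation.** `mode = "ideal"` is 0 for
  $D \le D_0$ and 1 elsewhere — the high-pass orientation, which is the
  only one consistent with the sharpening role of the filter.
* **Spectral convention.** Zero frequency centered
  (`fftshift`), distances in index units from the center of the
  native-size grid, no padding.
* **Post-filter rescaling.** Real part, negatives clipped to 0, linear
  rescale only if the maximum exceeds 255 — this keeps the filtered
  image on the original intensity scale so the subtraction is
  meaningful.
* **Otsu semantics.** Background is `pixels <= t`; ties break toward
  the smallest threshold; non-integer intensities are floored onto the
  8-bit grid before the sweep. A constant image is a degenerate
  histogram and an error.

## Segmentation: rotation-optimized integral projections

The row of minimum horizontal projection $H(i) = \sum_j f(i,j)$ marks
the gap between the upper and lower tooth rows — but only once the film
is rotated so the gap runs horizontally. The search therefore sweeps
rotation angles (default ±15° in 1° steps, matching typical clinical
tilt), computes the projection at each angle, and keeps the global
minimizer $(\theta, y) = \arg\min H_\theta(y)$. Columns of minimum
vertical projection $V(j) = \sum_i f(i,j)$ likewise separate adjacent
teeth.

Decisions the projection formalism leaves open, and how this package
resolves them:

* **Search band.** Rotation introduces zero-filled borders that would
  trivially minimize any projection; candidates are restricted to
  indices intersecting the rotated foreground's bounding box.
* **Tie-breaking.** Zero-score ties are generic (a narrow gap admits
  several exact-zero lines): ties break toward smaller `|angle|`, then
  smaller angle, then the index nearest the image center, then the
  smaller index. The sweep enumerates candidates in exactly that order
  and keeps the first strict minimum.
* **Multiple teeth.** The argmin yields one line; an unknown number of
  teeth is handled by recursive bisection. The best `(angle, column)`
  on a segment is accepted as a cut when its score is at most
  `valley_ceiling` (default 0.15) times the mean in-band column mass
  and both sides are at least `min_tooth_width` (default 8% of the row
  width) wide; accepted cuts recurse on both sides. This needs no
  prior tooth count and degrades to the single argmin for two teeth.
* **Resampling.** Nearest-neighbor on binary images (preserving the
  `{0, 255}` alphabet the projections sum over), bilinear on grayscale
  crops; zero fill everywhere; rotation is about the image center with
  unchanged extent.
* **Order of operations.** The row separator is found once on the whole
  binarized film; the film (grayscale and binary) is rotated to that
  angle and cut; tooth separators are then found per row
  independently, and crops are taken in the rotated frame.
* **Coordinates.** 1-based row/column indices and closed intervals,
  the R convention, throughout.

Each tooth is cropped as the axis-aligned hull of its two (possibly
oblique) separating lines; pixels on the far side of either line are
zeroed by half-plane tests so that fragments of neighboring teeth
inside the bounding box cannot mislead the classifier. Finally the
crop is cut at its middle column (odd widths: the left half gets the
extra column) into the left and right half images that findings are
judged on.

## The synthetic bitewing generator

`generate_bitewing()` draws two rows of superellipse crowns on
mid-intensity alveolar pedestals over a dark background, adds clipped
Gaussian noise, and rotates the whole scene. The default intensity
bands (background 15, alveolar 100, teeth 180, noise sd 8) reproduce
the three-band structure of clinical films and are separated by at
least three noise standard deviations, which makes Otsu binarization
well posed by construction. Findings are planted per tooth half:
restorations as radiopaque disks (intensity 250) near the occlusal
edge, caries as radiolucent disks (intensity 60) inside the crown.
Ground truth — row-gap band, interdental gap intervals, per-tooth
boxes, per-half labels, and the pre-rotation canvas — is recorded
exhaustively, so segmentation can be scored without any annotation.

Geometry choices worth stating:

* The occlusal gap height is about 2% of the image height. A taller
  gap would admit exact-zero separating lines over a range of angles,
  making the minimizing angle unidentifiable at the 1° sweep
  resolution; the narrow gap pins it down.
* Interdental gaps are 8–14 px wide and carry exactly zero foreground
  mass in the noiseless limit, so vertical-projection separators are
  exact there.
* Crown shapes, the noise model and the lesion geometry are package
  inventions; they emulate the intensity structure of bitewings, not
  their anatomy. Passing recovery tests on these scenes demonstrates
  that the projection search, masking and bookkeeping are correct —
  not that the pipeline segments arbitrary clinical films, which show
  overlapping crowns, uneven exposure and restorations bridging
  interdental gaps that the generator does not emulate.

When scoring segmentation against ground truth
(`segmentation_recovery()`), a separating line is mapped back into
pre-rotation coordinates and counted as inside a gap with one pixel of
slop, the point spread of bilinear resampling against an integer-grid
truth band.

## Database construction

Clinical findings are rare and unbalanced (of 3716 half images in the
population this package models, 610 carry restorations and only 88
caries). Each finding gets an independent binary database: positives
are augmented (randomly parameterized flips, ±10° rotation, ±10% zoom,
±10 px translation, 0.8–1.2 contrast gain, ±20 brightness) up to 350,
or subsampled down to 350 when abundant; negatives are subsampled to
350; every image is standardized to 200 × 100 (rows × columns — teeth
are taller than wide) and contrast-enhanced. 70% of each class goes to
training+validation (20% of that pool to validation), 30% to test.

Split assignment is made at the provenance-group level: an augmented
copy always shares its source image's split, which rules out
train/test leakage. Originals are preferred for the test set; only
when a class has fewer originals than the test quota (the caries case:
88 originals, 105 test slots) are whole provenance groups moved into
the test set to fill it. The alternative — restricting the test set to
originals only — is arithmetically impossible for a class with fewer
originals than its test quota, which is why the group-level rule was
chosen.

## The classifier

The judgment model is AlexNet modified in three places: the input
layer is 200 × 100 × 3 (the standardized half image replicated onto
three channels), the two hidden fully connected layers are 1280 wide,
and the output is 2-way. Kernels are canonical AlexNet (conv-1 11×11
stride 4; pools 3×3 stride 2; conv-2 5×5 pad 2; conv-3..5 3×3 pad 1),
local response normalization follows the first two ReLUs (depth 5,
α = 1e-4, β = 0.75, k = 2), dropout is 0.5, and the loss is 2-class
softmax cross-entropy. The realized per-layer extents are audited
against the plan at build time; under the floor arithmetic
`floor((in - kernel + 2 pad)/stride) + 1` the 200 × 100 input yields
conv-1 48 × 23 × 96 and pool-5 5 × 2 × 256 (2560 features entering the
fully connected stack).

Training is mini-batch stochastic gradient descent with momentum
(defaults: momentum 0.9, learning rate 6e-5, at most 100 epochs,
batch 64, validation patience 10 evaluated once per epoch). Batches
are drawn in seeded random order; runs are deterministic given the
seed on single-threaded BLAS. Weights initialize He-normal unless
pretrained parameters are supplied (`weights =` in `build_alexnet()`,
the transfer-learning entry point); nothing in the package requires a
download, and all tests run from random initialization. When early
stopping triggers, the final-epoch weights are kept (no best-epoch
snapshot).

The engine itself is written in base R: convolutions are im2col
gathers with precomputed index tables followed by single BLAS matrix
products, and every layer's analytic gradient is tested against
numerical differentiation. On one CPU a full forward+backward pass
costs about a second per image, which sets the problem sizes used in
the test suite: the learning-sanity check trains on 40 separable
synthetic half images — per seed, the same crown with and without a
bright restoration blob, so the blob alone carries the class — for 10
epochs in batches of 5 at learning rate 3e-4, with the dropout rate
set to 0 for that run (dropout's gradient noise dominates at such
small sample sizes; the layers themselves stay in the architecture
and default to 0.5). The sanity images are standardized but not
contrast-stretched: percentile stretching compresses the bright tail
where the blob lives and would largely erase the class signal it is
meant to carry. The production-scale defaults (350+350 images,
batch 64, 100 epochs) are practical on stronger hardware but are not
exercised by the tests.

Evaluation tallies argmax judgments into a 2 × 2 truth table reported
both as raw counts and row-normalized percentages, with accuracy
$(tp + tn)/\mathrm{total} \times 100\%$. Per-tooth reports phrase each
positive finding as a percentage (`"99.9% to be caries"`); a tooth
positive for both findings reports both, and a tooth below 50% on both
models is reported normal with the smaller of the two negative-class
probabilities.

## Known limitations

* The generator does not emulate overlapping crowns, exposure
  gradients, cusp anatomy or restorations that touch interdental
  gaps; recovery rates on synthetic scenes are an upper bound on
  clinical behavior.
* The recursive bisection assumes interdental valleys are deep
  relative to the mean column mass; crowded dentition with contact
  points would require a lower `valley_ceiling` and may still merge
  teeth.
* The CNN engine is single-image, single-threaded R; it is meant for
  correctness and desk-scale experiments, not production training
  throughput.
* Accuracy figures obtained on synthetic databases say nothing about
  clinical accuracy; they verify the machinery, not the medicine.
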