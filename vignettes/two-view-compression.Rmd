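---
title: "Two-view compressed residual classification of white-matter hyperintensity volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-view compressed residual classification of white-matter hyperintensity volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wmh2view)
```

## The problem

Neuromyelitis optica spectrum disorder (NMOSD) and multiple sclerosis (MS)
both produce white-matter lesions that appear hyperintense on T2-FLAIR MRI,
with spatial distributions that overlap heavily between the two diseases.
Telling them apart matters clinically — several MS therapies can worsen
NMOSD — but NMOSD is rare, so cohorts are small (order 40–50 subjects per
class), and a subject's evidence is an entire 3D volume rather than a
single informative slice.

That combination is hostile to conventional 3D convolutional networks: a
3D ResNet-18 carries about 33M learnable parameters and must be trained
from scratch, because no 3D pretrained backbone comparable to the ImageNet
2D models exists. This package implements the alternative studied here: a
*compression block* folds one spatial axis of the volume into the channel
dimension of a single strided 2D convolution, two such blocks (folding two
different axes) are concatenated, and a standard 2D residual backbone —
optionally initialized from pretrained weights — classifies the fused map.

## The model

For a cube volume $x(h, w, l)$, the two views are

$$x_1(c, w, l) \quad\text{(axis } h \text{ folded to channels)},\qquad
  x_2(c, h, l) \quad\text{(axis } w \text{ folded)},$$

and each is processed by one compression block

$$y_i = \mathrm{ReLU}\!\left(\mathrm{BN}\!\left(\mathrm{conv2d}(x_i)\right)\right),
  \qquad i = 1, 2,$$

with a $7 \times 7$ kernel, stride 3 and 32 output channels, so a
100-voxel spatial extent becomes $\lfloor(100 - 7)/3\rfloor + 1 = 32$
positions. The fused map $y = \mathrm{concat}(y_1, y_2)$ has 64 channels
and enters an 18- or 34-layer residual backbone ($y = F(x, \theta) + x$
blocks) at its first pooling stage: the usual $7\times7$ stem convolution
and its normalization are omitted, because the fused 64-channel map is
already exactly what the first residual stage consumes. Global average
pooling, dropout (rate 0.15) and a 2-unit affine layer produce the logits.
A conventional 3D residual network of matching depth is provided as the
baseline.

### The reference configurations and parameter accounting

The published complexity table pins down the four totals to the parameter:
11,475,330 and 21,583,490 for the two-view models at depths 18 and 34, and
33,161,986 and 63,471,618 for the 3D baselines. Working backward from
those totals fixes the few design choices the text leaves open, and the
package adopts exactly that configuration:

* each per-view compression convolution takes **98 input channels**, has
  **no bias**, and its batch normalization is **non-affine**
  ($7\cdot7\cdot98\cdot32 = 153{,}664$ weights per view);
* the 2D backbone is the standard residual layout — bias-free block and
  projection convolutions, affine normalization — with a 2-unit output
  head (1,026 parameters);
* the 3D baseline keeps a bias on its single-channel $7^3$ stem and on the
  $1^3$ downsample projections, with bias-free $3^3$ block convolutions
  and affine normalization throughout.

`count_learnable_parameters()` reproduces all four totals exactly, and the
acceptance script recomputes them by building each model:

```{r params, eval = FALSE}
count_learnable_parameters(build_model(model_spec("two_view_2d", 18)))
#> [1] 11475330
```

The 98 input channels also resolve how a $100^3$ cube feeds the blocks:
each branch center-crops its folded axis by one voxel per side
(100 → 98) immediately before folding, leaving the two spatial extents at
100. This reconstruction is the minimal reading consistent with the
printed totals; it additionally makes standard 2D backbone weights
drop-in compatible for transfer (`load_pretrained_backbone()`), since no
stem exists to conflict with the 64-channel entry point. Normalization
running statistics are buffers, never parameters, and are excluded from
all counts.

The network input is configurable (`input_mode`): the binary lesion mask
(the default, reflecting that the classifier operates on automated WMH
segmentations), the raw FLAIR intensities, or the mask-restricted FLAIR.
The study description does not fix this unambiguously, so it is a
parameter rather than a guess.

## Preprocessing

The pipeline mirrors the study's four steps, in `preprocess_subject()`:

1. **Crop**: the tightest bounding box of FLAIR voxels above a background
   threshold (default 0 — registered, skull-stripped exports pad with
   exact zeros). The kernel is computed on the FLAIR volume *only* and
   reused unchanged on the lesion mask, so the pair stays aligned. Whether
   the original "fixed crop kernel" was per-subject or cohort-wide is
   ambiguous; this implementation computes it per subject.
2. **Paired crop** of the mask with that same kernel.
3. **Resize** to a $100^3$ cube, done as an in-plane resize of each
   section followed by a resample across sections (mirroring per-section
   resizing), with linear interpolation for intensities and
   nearest-neighbour for masks — masks therefore remain strictly binary.
   Coordinates are corner-aligned, so an input already at the target size
   is returned bit-identical. Separable linear interpolation equals
   bilinear interpolation in-plane, and the constant-volume test pins the
   behaviour.
4. **Augmentation** by integer shifts (default at most 2 voxels per axis,
   zero-filling vacated voxels) and reflection (default only the
   left–right axis, exploiting anatomical symmetry), with FLAIR and mask
   receiving identical transforms. The study states shifting and flipping
   but no magnitudes; the defaults here are deliberately conservative.
   Augmentation is applied to training folds only — the study is silent,
   but anything else would leak.

Intensity volumes are min–max normalized per volume to $[0, 1]$ (constant
volumes map to 0); the study does not describe intensity scaling, so the
simplest convention is used and documented.

## Synthetic phantoms

The patient volumes are withheld for ethics reasons, so the package ships
a generator (`generate_phantom()`, `generate_cohort()`) whose *defaults
are the study conditions*: cohort sizes 47 MS / 41 NMOSD, and per-class
lesion burdens matching the reported normalized WMH loads — MS
0.66% ± 0.65% and NMOSD 0.26% ± 0.37% of intracranial volume. Each phantom
is an ellipsoidal brain with a central ventricle proxy; lesions are unions
of randomly oriented ellipsoidal blobs seeded in white matter with a
class-specific *periventricular affinity*, so confluent, irregular lesion
shapes arise from blob overlap.

Numerical choices worth knowing:

* **Truncated, calibrated burden draws.** The reported standard deviations
  are as large as the means, so a plain normal would frequently go
  negative. Fractions are drawn from a normal truncated at zero whose
  location parameter is solved (by `calibrate_truncnorm_mu()`) so the
  *post-truncation mean equals the reported mean exactly*; an uncalibrated
  truncation would bias MS burdens upward by ~27%. The realized standard
  deviation sits somewhat below the reported one — for the NMOSD
  sd/mean ratio (1.42) no zero-truncated normal can match both moments,
  so matching the mean (the quantity the calibration check compares) was
  chosen. Means are matched exactly in expectation; the Monte-Carlo
  calibration test verifies 50 draws per class against the configured
  means within two standard errors.
* **Exact voxel counts.** The final mask keeps exactly
  `round(fraction * brain_voxels)` of the highest-scoring blob-field
  voxels (ties broken by index), so every subject's recorded lesion
  fraction equals its mask voxel count divided by its brain voxel count
  as an identity, and the Monte-Carlo calibration is not polluted by
  placement discretization.
* **Spatial overlap as a dial.** Default periventricular affinity is 0.7
  for *both* classes: the two cohorts then differ only in burden
  distribution, with heavily overlapping spatial patterns — deliberately
  hard, matching the narrative that the two diseases' lesion
  distributions overlap. `easy = TRUE` switches to fractions 2% vs 0.2%
  and affinities 1 vs 0, a configuration a working classifier must
  separate; it exists to make end-to-end learning testable, not to mimic
  the clinic. The true overlap level in the study is only qualitatively
  described, so it is exposed as a parameter rather than fixed.

What the phantoms do *not* emulate: anatomy beyond the two ellipsoids,
acquisition physics, bias fields, registration error, or the demographic
covariates of the cohort table. A classifier separating easy-mode
phantoms demonstrates that the architecture, training loop and protocol
work — it says nothing about clinical accuracy, which is exactly why the
published accuracies on the patient cohort are out of scope here.

## Training and evaluation protocol

`train_model()` runs mini-batch SGD (momentum 0.9, batch size 4) on
2-class cross-entropy with the study's schedule: initial learning rate
0.01 reduced by 10% every ten steps, read as epochs —
`lr(e) = 0.01 · 0.9^⌊e/10⌋` — since iteration-level decay would collapse
the rate within a single epoch at this cohort size. Dropout (0.15) is
active only in training. The number of epochs per fold is never stated in
the study and is therefore a required configuration value. Momentum and
batch size are likewise unstated; 0.9 and 4 are conventional defaults at
this memory scale.

`make_fold_plan()` implements repeated 5-fold cross-validation (default
15 repeats): per repeat an independent shuffle is split into groups whose
sizes differ by at most one, so every subject is validated exactly once
per repeat. Folds are *random, not stratified*, as in the study
("randomly divided into five equal-sized groups"); stratification is
available behind a flag. `run_repeated_cv()` builds a fresh model per
(repeat, fold) — reloading pretrained backbone weights if configured —
trains on the other four groups and evaluates on the held-out group.
Per-repeat metrics pool the five folds' confusion counts (fold-size-robust;
per-fold averaging is available via `fold_average = TRUE` since the study
does not say which it used), and the aggregate reports mean ± sd across
repeats of accuracy, sensitivity and specificity. Sensitivity treats
NMOSD as the positive class by default (the rarer disease being
detected); the study does not state its convention, so it is configurable
and echoed in every report. Zero-denominator metrics are reported as
`NaN` with a warning rather than silently dropped.

Two structural invariants are checked directly from the provenance log of
every report: `check_no_leakage()` (train and validation ids disjoint for
every fold; each subject validated once per repeat) and
`check_metric_algebra()` (the reported metrics equal their defining
confusion-count ratios exactly).

## Numerical engine and problem sizes

No deep-learning framework is involved: convolution (2D and 3D) forward
and backward passes are im2col + GEMM in C++ (RcppArmadillo), with batch
normalization, pooling, dropout and the SGD/momentum update implemented
natively. The convolution paths are verified against direct
definition-level convolution oracles and central finite differences in
the test suite. He-uniform initialization for convolutions, zeros for
biases, everything deterministic under a supplied seed. The optimizer
updates parameters in place (the model owns its arrays); weights loaded
from an external source are copied first so the caller's arrays are never
mutated.

The test suite exercises the full 2-repeat × 5-fold, 20-epoch protocol on
an 80-phantom easy-mode cohort at cube side 32 (folded axes cropped to 30
channels, exactly as 100 → 98 at full size). The compression geometry
scales with the side, the backbone is the full 11.5M-parameter depth-18
network either way, and side 32 keeps the complete protocol to a few
minutes on a single CPU; the shape law is separately verified across
spatial extents 16–128, and the full-size forward pass and parameter
accounting run at side 100.

## Known limitations

* The compression block uses exactly one convolution per view — the
  wording "the first convolution layer" could admit more, but the printed
  parameter totals admit exactly one.
* Volumes are consumed in stored axis order; no reorientation to a
  canonical anatomical frame is attempted (the study never mentions
  orientation handling). Inputs registered differently must be reoriented
  upstream.
* ImageNet pretraining itself is out of scope: `load_pretrained_backbone()`
  consumes a named-array export of standard 2D residual stage weights and
  validates names and shapes strictly, but the package does not ship such
  weights.
* The phantom generator supports protocol validation, not clinical
  inference; no claim about patient-cohort accuracy follows from any
  number this package produces.
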