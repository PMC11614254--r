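---
title: "Methods: models, protocols and design choices in ctseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, protocols and design choices in ctseg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ctseg` implements a model-assisted annotation workflow for abdominal CT:
convert scans to a windowed slice store, train a 2-D segmentation network,
propose masks for new scans, and track a human reviewer's corrections so the
reviewed data can retrain the model. This vignette records the scientific and
numerical decisions behind each stage, in enough detail that a maintainer can
judge (and revisit) them.

## 1. From DICOM to the slice store

CT voxels are calibrated to Hounsfield units via the per-file rescale slope
and intercept *before* any windowing. This ordering is essential: a window
"center of 50 HU" is only meaningful in HU space, not in raw stored values.
Slices are ordered by the projection of the image position onto the slice
normal (the cross product of the row and column direction cosines), with the
instance number as tie-break and fallback; the stack is stored in ascending
order of that projection.

Windowing maps HU value $x$ to stored intensity with the linear VOI
convention

$$y = \Big(\frac{x - (w_c - 0.5)}{w_l - 1} + 0.5\Big)(y_{max}-y_{min}) + y_{min},$$

so the map hits $y_{min}$ and $y_{max}$ exactly at
$x = w_c - 0.5 \mp (w_l-1)/2$; values beyond the edges clamp to the extremes.
Defaults are the abdominal soft-tissue window $w_c = 50$ HU, $w_l = 400$ HU
into the full 16-bit range $[0, 65535]$. Two numerical choices are fixed
here because no convention dictates them: rounding is to the nearest integer
with ties away from zero (so the window midpoint at $x = 49.5$ maps to 32768
in 16-bit and 128 in 8-bit), and clamping happens before rounding, which
keeps the edges exact.

Slices are stored as 16-bit grayscale PNGs (lossless, bit-exact round trip),
masks as 8-bit PNGs in the `{0, 255}` dialect; a reader encountering any
other value in a mask file fails rather than guessing. File names are
`<patientID>_<sliceIndex>.png` with 0-based, 4-digit zero-padded indices.
The PNG encoder is implemented in the package (deflate via R's zlib
bindings, explicit CRC32) because no 16-bit-capable PNG writer is otherwise
available to R; decoding goes through `png::readPNG`, which serves as an
independent check of the encoder in the tests. The DICOM layer likewise
implements the little-endian explicit/implicit-VR subset needed for
single-frame CT series, plus a fixture writer used to generate synthetic
series in tests; sequences with undefined length and compressed transfer
syntaxes are out of scope and rejected loudly.

## 2. The segmentation network

The model is the standard encoder–decoder design for organ segmentation: a
residual encoder (basic-block ResNet-18 or -34 layout; 34 is the default)
produces features at scales 1/2 … 1/32, and either

* a **U-Net decoder** — five upsample blocks, each concatenating the
  encoder's skip features and applying two conv–BN–ReLU layers — or
* an **FPN decoder** — 1×1 lateral projections merged top-down by addition,
  per-level segmentation blocks summed at 1/4 scale, then upsampled —

ends in a 3×3 convolution and a per-pixel sigmoid. Inputs are single-channel
slice intensities divided by the bit-depth maximum into $[0,1]$; spatial
dimensions must be divisible by 32 (five 2× downsamplings). The network is
fully convolutional, so inference size need not match training crop size.

`width_multiplier` scales every channel count. Width 1.0 is the full
architecture (64/64/128/256/512 encoder channels); widths 1/4 and 1/16 give
desk-scale variants that train and test in seconds to minutes on one CPU.
The engine itself is written in R: convolutions are im2col gathers followed
by BLAS matrix multiplies, with analytic backward passes for every layer
(verified against central differences in the test suite). There is no GPU
path; the package's scope is desk-scale training and full-scale *inference*
plumbing, not 24-hour full-scale training runs.

Initialization is seeded He-normal for convolutions. Each residual block's
final batch-norm gain starts at zero, so a deep random-init network begins
near the identity; this is what makes from-scratch training stable at the
depths used here. Batch norm uses momentum 0.1 for its running statistics;
inference always uses running statistics, which makes probability maps
independent of batch composition. Pretrained encoder weights are supported
only as a local file hook (`build_model(..., encoder_weights = )`); there is
deliberately no download path, so builds are reproducible offline.

Binarization uses threshold 0.5 with `>=` inclusion — a pixel at exactly the
threshold is foreground. The choice is arbitrary but must be fixed for
reproducibility; it is asserted in tests.

## 3. Loss

Training minimizes the Focal Tversky loss on soft counts pooled over the
batch:

$$TP = \textstyle\sum_i p_i t_i,\quad FP = \sum_i p_i(1-t_i),\quad
FN = \sum_i (1-p_i)t_i,$$

$$\mathrm{TI} = \frac{TP + s}{TP + \alpha FP + \beta FN + s},\qquad
\mathrm{FT} = (1-\mathrm{TI})^\gamma,$$

with defaults $\alpha = 0.7$, $\beta = 0.3$, $\gamma = 0.75$, $s = 1$.
Weighting false positives above false negatives ($\alpha > \beta$) counters
the tendency of small-organ models to over-segment; $\gamma < 1$ amplifies
gradients on hard examples; the additive smoothing keeps the index defined
(and the loss zero) when both masks are empty. With $\alpha = \beta = 0.5$
and vanishing smoothing the index reduces to the Dice coefficient, and with
$\gamma = 1$ the loss reduces to 1 − soft-Dice — both limits are tested.

One form question deserves a note: the focal exponent is sometimes printed
as $\mathrm{TI}^\gamma$ without the "1 −". That expression is *maximal* for a
perfect prediction and cannot serve as a loss; `ctseg` therefore defaults to
$(1-\mathrm{TI})^\gamma$ and offers the literal form behind
`loss_config(form = "printed")` for fidelity experiments only.

Because $\gamma < 1$ makes $d\,\mathrm{FT}/d\,\mathrm{TI}$ singular as
$\mathrm{TI} \to 1$, the backward pass clamps $1-\mathrm{TI}$ at $10^{-8}$.

## 4. Augmentation

Each configured transform fires independently with probability 0.5 per
sample. Geometric transforms are composed into a single inverse-mapped
affine about the image center and applied identically to image (bilinear)
and mask (nearest-neighbour), so the pair can never drift apart; a random
crop (center crop when the crop transform does not fire) fixes the output
size. Intensity transforms touch the image only.

Defaults, with units and rationale:

| transform | default | notes |
|---|---|---|
| rotation | ±5° | anatomical augmentation range; degrees, not radians — a ±5 rad range would be anatomically meaningless |
| scale | 0.6–1.4 | isotropic zoom |
| translation | ≤80 px | both axes |
| random crop | 448×448 px | training crop for 512×512 slices |
| h/v flip | p = 0.5 each | parameter-free |
| gamma | 0.5–1.8 | exponent on the [0,1] scale |
| brightness/contrast | 30–100 intensity units | specified on the 8-bit scale (÷255), random sign each |
| salt & pepper | 0.1 | fraction of pixels replaced by 0/1 |
| Gaussian noise | 0.5 | percent of dynamic range (sd 0.005) |
| Gaussian blur | kernels {3,7,11}, σ ∈ [1,10] | |
| median blur | kernels {3,7,11} | |
| cutout | 20% | of image area, zeroed square, image only |

Unit-less ranges ("arbitrary units") in common augmentation specifications
are pinned here to explicit conventions — the 8-bit intensity scale for
brightness/contrast, percent-of-range for noise — and all are overridable in
`augmentation_config()`. Geometric operations preserve mask area to within
~10% for small rotations (nearest-neighbour resampling; property-tested).

## 5. Training protocol and cross-validation

The full-scale protocol is `train_config()`: 50 epochs, batch 16, Adam with
initial learning rate and weight decay $10^{-4}$, learning rate ×0.1 after
epochs 20, 30 and 40 (0-based epoch convention: `lr_at_epoch(20)` is already
reduced). Model selection keeps final-epoch weights; no early stopping.
Empty-slice filtering (`filter_empty_slices`) drops slices whose mask has no
foreground, the usual second-round practice once a reviewed dataset exists.

The desk-scale protocol is `desk_train_config()`: 30 epochs, batch 8,
initial rate $3\times10^{-3}$ with one ×0.1 step after epoch 25. The hotter
rate is needed because a randomly initialized narrow model sees only ~120
optimizer steps in such a run; the full protocol's $10^{-4}$ assumes a
pretrained encoder and tens of thousands of slices. With it, a width-0.25
model reliably overfits a few dozen 64×64 phantom slices to a training Dice
above 0.9, which is the package's capacity check.

Cross-validation is grouped at the patient level: patients are shuffled with
a seed and greedily assigned (largest slice count first, ties to the lowest
fold) to the currently lightest validation fold. No patient's slices ever
appear on both sides of a fold, also after `merge_datasets()` (sources keep
separate patient namespaces). A held-out test split (`holdout_split`,
default 20% of patients, unstratified) precedes folding. Folds are trained
independently and reported separately — there is no ensembling.

Reproducibility: initialization, shuffling and augmentation all derive from
explicit seeds; pure-R arithmetic makes a run deterministic for a fixed seed
and BLAS.

## 6. Evaluation conventions

Segmentation metrics pool pixel counts over a whole scan and compute
DSC/recall/precision once per scan (per-volume convention); a per-slice mode
exists. Degenerate cases are fixed conventions, not errors: both masks empty
→ DSC 1; empty prediction against non-empty truth → recall 0, DSC 0,
precision 1 (no false positives were made); the symmetric rule for recall.
Dataset summaries report mean ± sample SD (n−1).

Slice-level detection asks only "do the masks overlap by ≥1 pixel": truth
non-empty and overlap → TP; truth non-empty, no overlap → FN *even when the
prediction is non-empty elsewhere* (the clinical miss dominates; the slice
is not double-counted as FP); truth empty → FP/TN by prediction. Ratios
with zero denominators are reported missing, never as 0.

## 7. Annotation sessions

A session is an event-sourced log: model proposals plus an append-only list
of reviewer events (`accept`, `replace`, `add_region`, `erase_region`,
`create`), each carrying an externally supplied elapsed time. Timing is
never measured inside the package — summaries must be deterministic and
testable, and in production the elapsed times come from the UI's clock.
Replaying an exported log reproduces the final masks bit-exactly; this
property is the backbone of the JSON export/import format and is
property-tested on random sessions.

Summary conventions: `total_slices` counts annotated slices (non-empty final
mask), the convention under which annotation workloads are reported;
"accepted without revision" is counted per slice (an accept with no later
edit on that slice); all ratio rows (time per slice, averages per scan) are
derived from the logged totals at report time — stored ratios are never
authoritative — and reported at 1 decimal, rounded half away from zero.
Speed-up between tools is the ratio of manual to assisted time per slice,
computed by default from the rates at reporting precision (matching how one
reads a published summary table; `digits = NULL` uses exact rates). Across
several datasets the pooled ratio (from summed totals) and the unweighted
mean of per-dataset ratios answer subtly different questions and can differ
by several tenths; `speedup_report()` always prints both rather than
privileging either.

## 8. The phantom generator

`generate_phantom()` emulates the *structure* of an abdominal CT dataset: a
soft-tissue body ellipse (default 40 HU) in air (−1000 HU), an elongated
rotated super-ellipse target at 90 HU — portal-venous pancreas-like
contrast of only ~50 HU against background — whose in-plane width tapers
head-to-tail and whose per-slice area tapers over a contiguous central run
of slices, plus distractor blobs within ±15 HU of the target that never
overlap the ground truth, and Gaussian HU noise (sd 10). Scans with and
without the organ, and variable per-scan slice counts, mirror how real
datasets mix. The exact shape family is arbitrary; what matters is that the
ground truth is unambiguous, the contrast is realistically low, and
generation is bit-deterministic per seed.

What the phantom does *not* emulate: reconstruction kernels, beam hardening
and streak artifacts, anatomical context (organs with boundaries that touch
the target), pathology-induced shape change, and inter-scanner intensity
variation. Passing tests on phantoms therefore demonstrate that the
pipeline's mechanics are correct — calibration, geometry, loss, optimizer,
bookkeeping — not that the default model generalizes to clinical CT; the
held-out phantom Dice in the acceptance run (typically well below the
training Dice) makes the overfit/generalization gap visible rather than
hiding it.

## 9. Problem sizes used in tests and the acceptance script

Chosen as the smallest sizes that still exercise every code path: 16×16
grids for oracle comparisons (100 for windowing, 1000 mask pairs for
metrics), width-1/16 models at 64×64 for contract tests, one width-1/4
model on 32 organ-bearing 64×64 phantom slices for the 30-epoch capacity
check, 10-scan phantom datasets (2 organ-absent) with a 6/4 train/hold-out
split for end-to-end evaluation, and 50 random sessions for the
event-sourcing property. The acceptance script reruns the same computations
from scratch under a caller-supplied seed and writes every quantity as JSON.

## 10. Known limitations

* Training at clinical scale (512×512, width 1.0, tens of thousands of
  slices) is out of reach of the pure-R engine; the package trains
  desk-scale models and *runs* full-scale inference, slowly.
* Batch norm with batch size 1 degenerates (the package requires ≥2 samples
  per training batch to be meaningful); inference is unaffected.
* The DICOM subset excludes compressed transfer syntaxes, multi-frame
  enhanced CT and non-axial reformats.
* The FPN decoder follows the common segmentation-FPN shape but is not a
  weight-compatible port of any specific implementation.
* Phase filtering (e.g. portal venous only) is a manifest tag; the package
  does not classify acquisition phases.
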