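---
title: "Curriculum learning with mixed mammography annotations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curriculum learning with mixed mammography annotations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(curripatch)
```

This vignette is the package's own account of the method it implements: the
model, the procedure, every tunable that matters, the numerical conventions,
and what the synthetic phantom cohort does and does not tell you about real
mammography data.

## The supervision problem

Screening mammography gives two views per breast (craniocaudal, CC, and
mediolateral oblique, MLO). Image-level cancer labels are abundant —
pathology and follow-up settle them — but lesion *bounding boxes* require
radiologist time. The pipeline treats the box-annotation fraction as the
experimental variable: a cohort in which a fraction `s` of patients carries
boxes ("strong" tier) and the rest only image labels ("weak" tier) is
trained with a curriculum whose early stages consume only strong cases and
whose final stage consumes everything. `s = 0` *is* the weakly supervised
baseline — the same code path with the patch stages skipped, not a separate
implementation.

## Preprocessing: finding the breast

Raw mammograms are mostly empty background. A square window
(`scan_patch_size`, default 400 px) slides at `scan_stride` (default 80 px)
across the image; a window is *relevant* when the fraction of its pixels
brighter than `background_cutoff` (default 0.02 on the [0, 1] scale) exceeds
`black_threshold` (default 0.30). The phrase "black threshold of 30 %" is
ambiguous between bounding black pixels and bounding non-black pixels; both
readings are exposed (`threshold_on = "nonblack"` (default) or `"black"`),
and the default reads: discard a window once 70 % or more of it is empty.
The largest 8-connected component of relevant windows is taken as the
breast; ties are broken by covered pixel area, then by top-left-most
bounding box, so the result is deterministic. The region is expanded to
cover every ground-truth box (no annotation may be cropped away), padded
with zeros to a square — symmetrically, the smaller pad on the left/top for
odd deficits — and bilinearly resized (EBImage) to `target_size`
(default 1024).

Box coordinates are 0-based, half-open, `x` = column, `y` = row. They are
shifted by the crop/pad offsets and scaled by `target_size / input_size`,
rounding half away from zero. The recorded transform makes the mapping
invertible: one pixel of round-trip error per coordinate is guaranteed when
the resize scale is at least 0.5, which holds whenever the padded crop is no
larger than twice the network input — the regime the pipeline is designed
for. (At more extreme down-scales the inverse is still correct to
`0.5 / scale` pixels; nothing in the pipeline consumes inverted boxes, the
transform exists for provenance and visualization.)

## Patch labeling

A preprocessed image is tiled on a regular grid (stride = patch size by
default; a final flush row/column covers the far edge). Each tile gets
exactly one verdict:

* **skipped** — fails the same tissue-relevance rule as the scan windows
  (peripheral, tissue-poor tiles; tested *before* any overlap logic);
* **positive** — more than 50 % of the tile lies inside the union of
  ground-truth boxes;
* **negative** — less than 10 %;
* **ignored** — overlap in `[0.1, 0.5]`, endpoints included.

Overlap is computed against the *union* of boxes (multi-lesion images must
not double-count) with exact integer arithmetic — intersection areas are
integers, and the 10 %/50 % comparisons are done as `10·area∩ < area` and
`2·area∩ > area`, so the endpoint behavior is bit-exact, not
floating-point-lucky. Negatives are mined from both the normal tissue of
positive cases and from negative strong-tier cases, then down-sampled to a
1:1 negative:positive ratio by a seeded draw (`balance`); weak-tier cases
contribute nothing to patch stages, which is the definition of weak
supervision here.

## The backbone

The classifier is a stack of 3×3 convolution blocks (ReLU, 2×2 average
pooling after the early blocks) closed by *global* average pooling and a
linear two-class head. Global pooling is the load-bearing choice: the
feature vector has fixed length for every input side, so one set of weights
trains on 16-px patches and classifies 1024-px images. Two variants exist:
`tiny` (three blocks, 8/16/32 channels, ≈6k parameters, minimum input 8 px)
— the trainable desk-scale model — and `reference` (four blocks,
32/64/128/256 channels), a structural stand-in for a production-scale
classifier that the test suite exercises shape-wise across 128–1024 px
inputs. Weights are He-initialized from a seed; the head starts at zero so
an untrained model outputs probability 0.5. Whether to start from generic
pretrained weights is left open deliberately; seeded random initialization
is the default and the only option shipped.

Forward and backward passes are exact, hand-derived, and implemented with
im2col + BLAS (RcppArmadillo); the test suite checks backprop against
central finite differences at 1e-4 relative tolerance.

## The curriculum

`curriculum_config()` defaults follow the full-fidelity schedule: patch
stages 128/256/512 at 100 epochs each, then 15 full-image epochs, Adam at a
fixed learning rate of 1e-05, cross-entropy loss, random flips and
rotations. Rotations are restricted to multiples of 90° so augmentation
never interpolates pixels and never perturbs a patch's label. Weights
persist across stages ("one network, four stages"); the Adam state is reset
at stage boundaries — the conservative reading where stage boundaries are
genuine restarts — with `reset_optimizer = FALSE` available. The baseline's
epoch budget is genuinely unspecified in this design space: by default it
trains only the final stage (`baseline_epochs = final_epochs`), and a larger
matched-updates budget can be configured; neither option is claimed to be
the historically "correct" one.

Each configuration is run `n_runs` times (default 10) from distinct seeds;
every downstream metric is reported as mean ± sample SD (n−1; a single run
reports SD 0 and is flagged).

## Evaluation

The unit of evaluation is the *breast*: the predicted probabilities of its
available views (CC, MLO) are averaged — ipsilateral aggregation — and
thresholded at 0.5 (the threshold is configurable; nothing in the method
pins it). Recall, precision and F1 are reported on the 0–100 scale; zero
denominators score 0 with a degeneracy flag rather than erroring, because
early-training models legitimately predict one class.

## Grad-CAM and the ground-truth overlap ratio

Saliency is Grad-CAM at the final convolutional stage: channel weights are
the spatial means of the target-logit gradient, the weighted activation sum
is rectified, bilinearly upsampled to the input size, and min–max
normalized. With a global-average-pooling head the channel weights are
exactly `head_weight / (H'·W')`, which makes the implementation analytically
checkable — the suite verifies a hand-derived closed form on an
identity-kernel toy network and finite differences on the tiny backbone.

Explainability is scored by the ground-truth overlap ratio: select the
top-valued saliency pixels, count how many fall inside the rasterized union
of the case's boxes, divide by the total ground-truth pixel count, times
100. The metric is defined only for cancer cases. "Top pixels" needs a
budget: the default budget is *the case's own ground-truth pixel count*, the
fairest bounded choice — a perfect map scores exactly 100, and the score
cannot be inflated by selecting more pixels (the ratio is monotone
non-decreasing in the budget, so any fixed larger budget only flatters the
model). A top-5 % alternative is configurable. Ties at the cut value are
broken in row-major order, so masks are deterministic. Because the top-pixel
rule is a package choice, absolute overlap-ratio values are comparable
*within* this package's regimes, not against other implementations.

## The phantom cohort: what it emulates, what it does not

No clinical mammograms ship with this package. The generator emulates the
*structure* of a balanced screening cohort — per-patient CC+MLO views of
both breasts, 50 % cancer prevalence, lesions planted in both views of the
affected breast with mildly jittered geometry, per-patient annotation tiers,
patient-level 75/25 development/test splits — on images that are breast-
shaped bright regions on near-zero background with additive Gaussian noise.
Lesions are discs at `foreground + lesion_contrast`, so their tight
bounding boxes are recoverable by pixel scan, and each patient draws from an
RNG stream derived from the master seed, so enlarging a cohort never
reshuffles existing patients.

What the phantom deliberately does **not** model: parenchymal texture,
pectoral muscle, vendor physics, compression artifacts, microcalcification
morphology, lesion-size or density distributions calibrated to any clinical
population (none are published for the cohort structure being emulated —
the phantom's lesion parameters are placeholders, chosen for resolvability,
not realism). Consequently, passing the pipeline's tests demonstrates that
the *machinery* is correct — labeling rules, staging, aggregation, metrics,
saliency — and that curriculum ordering emerges when localized supra-
threshold signal exists. It does not demonstrate clinical-grade detection,
and absolute metric values on phantoms exceed anything attainable on real
data; on the phantom's trivially separable lesions curriculum-100 reaches
F1 ≈ 100 while a 3-epoch baseline sits at 0.

## Desk-scale preset and problem sizes

The full-fidelity schedule is a GPU-scale computation. `desk_preset()`
preserves its structure at laptop size, and these are the problem sizes the
package's own experiments (and its test suite) use: 60 patients (240
views), native phantoms 192×160, network input 128², patch stages 16 → 32
at 6 epochs each (≤400 samples per stage), 3 full-image epochs, learning
rate 1e-3 (the 1e-05 default is matched to 100-epoch stages; at 6 epochs it
would leave the network at initialization), batch 8, tiny backbone, 5
repeated runs, regimes {0, 0.2, 1.0}. Lesions are proportionally larger
than clinical lesions (radius 28–36 px native) so that the >50 %-overlap
rule remains satisfiable at every patch size at this resolution.

## Numerical conventions and degenerate inputs

* Boxes: 0-based, half-open; rounding half away from zero everywhere a
  coordinate is scaled.
* A blank image (no relevant scan window) raises a typed `empty image`
  error; it signals corrupt input, not a scorable case.
* An all-zero Grad-CAM map (head ignores all channels) is returned as all
  zeros with a `degenerate` flag and yields an empty top-pixel mask and an
  overlap ratio of 0.
* Exactly-tied overlap fractions (10 %, 50 %) are ignored-tier by
  definition and tested exactly.
* Training aborts with a typed error on single-class stages and on
  non-finite loss.
* All randomness — cohort generation, tier assignment, splits, negative
  subsampling, shuffling, augmentation, weight init — flows from explicit
  seeds; identical configuration and seed reproduce byte-identical metrics
  files.

## Known limitations

* The backbone is a generic small CNN, not a replica of any production
  architecture; the `reference` variant is exercised structurally, not
  trained.
* Phantom realism as above; no claim transfers to clinical data without
  retraining and re-evaluation on real cohorts.
* The overlap ratio's top-pixel budget is a package convention (see above).
* Patch stages interleave nothing: sizes are strictly sequenced; per-epoch
  size mixing is out of scope.
* No learning-rate schedules, early stopping, or pretrained weights.
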