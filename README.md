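# curripatch

Annotation-efficient curriculum learning for patch-based breast-cancer
detection in screening mammograms.

## The problem

Deep-learning mammography classifiers work best with *strong* supervision —
radiologist-drawn bounding boxes around every lesion — but boxes are
expensive, while *weak* image-level labels (cancer / no cancer) are nearly
free. `curripatch` implements a staged curriculum that mixes the two: a
scale-invariant CNN is first trained on small image patches labeled from the
available bounding boxes (128 → 256 → 512 px on a 1024 px input), then
finished on full images with weak labels only. Varying the fraction of
box-annotated cases yields the familiar regimes:

* **baseline** — 0 % boxes: the final, weakly supervised stage only;
* **curriculum-20 / 40 / 100** — patch stages trained on 20 / 40 / 100 % of
  cases with boxes, final stage on everything.

The package covers the full pipeline:

1. **Phantom cohorts** (`phantom_config()`, `generate_cohort()`,
   `assign_annotation_tiers()`) — seeded synthetic screening cohorts: CC and
   MLO views of both breasts per patient, breast-shaped foreground, planted
   lesions with tight ground-truth boxes, per-patient strong/weak tiers.
2. **Preprocessing** (`scan_params()`, `preprocess_cohort()`) — a sliding
   window (400 px, stride 80) marks tissue-relevant regions (a window counts
   when more than 30 % of its pixels are non-black); the largest 8-connected
   region is cropped, zero-padded to a square and bilinearly resized to
   1024², with all boxes co-transformed and the transform recorded for exact
   inversion.
3. **Patch labeling** (`tile()`, `overlap_fraction()`, `classify_patch()`,
   `build_patch_dataset()`) — exact rational overlap against the *union* of
   boxes: positive above 50 %, negative below 10 %, ignored in `[10 %, 50 %]`
   (endpoints included), tissue-poor tiles skipped.
4. **Backbone + training** (`backbone_config()`, `run_curriculum()`,
   `repeat_runs()`) — a global-average-pooled conv net (any square input
   size, one weight set across all stages), two-class cross-entropy, Adam at
   a fixed learning rate, flip/90°-rotation augmentation, repeated seeded
   runs.
5. **Breast-level evaluation** (`breast_predictions()`, `prf1()`,
   `summarize_runs()`) — ipsilateral CC/MLO probabilities averaged per
   breast, thresholded at 0.5; recall / precision / F1 on the 0–100 scale as
   mean ± SD over runs.
6. **Explainability** (`grad_cam()`, `top_pixel_mask()`, `overlap_ratio()`,
   `cohort_overlap()`) — Grad-CAM saliency from the final conv layer; the
   **ground-truth overlap ratio**

   ```
   ratio = 100 · (top-saliency pixels inside ground-truth boxes)
                 / (total ground-truth box pixels)
   ```

   scored for cancer cases only, 100 = perfect localization, 0 = worst.

Everything is driven by one configuration (`pipeline_config()`, YAML
round-trip) and runs end-to-end via `run_pipeline()`. A thin CLI lives at
`inst/cli/curripatch.R` (`simulate | preprocess | train | evaluate |
explain | all`).

## Worked example

The desk-scale preset is the same pipeline at laptop size: a 60-patient
phantom cohort, 128 px inputs, patch stages 16 → 32, the tiny backbone:

```r
library(curripatch)

res <- run_pipeline(desk_preset(n_runs = 2, regimes = c(0, 1.0), seed = 1))
res$per_run
#> # A tibble: 4 × 7
#>   regime         strong_fraction  seed recall precision    f1 overlap_ratio
#>   <chr>                    <dbl> <int>  <dbl>     <dbl> <dbl>         <dbl>
#> 1 baseline                     0     1    0           0   0             0
#> 2 baseline                     0     2    0           0   0             0
#> 3 curriculum-100               1     1  100         100 100            90.7
#> 4 curriculum-100               1     2  100         100 100            91.5
```

Read: after three weak-label epochs the baseline has not yet escaped the
majority class (all-negative predictions; recall 0 is flagged as
degenerate), while the box-pretrained curriculum-100 model separates the
held-out test breasts perfectly and its Grad-CAM top pixels cover ~91 % of
the ground-truth lesion pixels. On the phantom's high-contrast lesions the
curriculum effect is therefore much starker than on clinical data, where the
same ordering appears with far smaller margins. `autoplot(res)` draws the
regime comparison; `tidy(res)` returns the long metric table.

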