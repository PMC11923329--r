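#' Patch grid specification
#'
#' Training patches come in three sizes (128, 256 and 512 on the 1024 input);
#' other sizes are allowed for scaled-down experiments. The stride defaults
#' to the patch size (non-overlapping tiling); a smaller stride gives denser
#' sampling.
#'
#' @param patch_size Patch side in pixels.
#' @param stride Grid step in pixels (defaults to `patch_size`).
#' @return A validated `patch_spec` list.
#' @export
patch_spec <- function(patch_size, stride = patch_size) {
  s <- structure(list(patch_size = as.integer(patch_size),
                      stride = as.integer(stride)),
                 class = "patch_spec")
  if (s$patch_size < 1 || s$stride < 1) abort("patch size and stride must be >= 1")
  s
}

#' Tile an image into patch boxes
#'
#' Regular grid starting at (0, 0) stepping by the stride, with a final row
#' and column flush to the far edge when the grid does not reach it. Boxes
#' are unique.
#'
#' @param image_size Side of the (square) image in pixels.
#' @param spec A [patch_spec()].
#' @return Box tibble of patch positions.
#' @export
tile <- function(image_size, spec) {
  if (image_size < spec$patch_size) abort("image smaller than patch size")
  starts <- grid_starts(image_size, spec$patch_size, spec$stride)
  g <- tidyr::expand_grid(y0 = starts, x0 = starts)
  boxes(g$x0, g$y0, g$x0 + spec$patch_size, g$y0 + spec$patch_size)
}

#' Fraction of a patch covered by ground-truth boxes
#'
#' Area of the intersection between the patch and the *union* of the
#' ground-truth boxes, divided by the patch area. Computed exactly on
#' integer pixel coordinates (coordinate compression), so threshold
#' comparisons at 0.1 and 0.5 are exact.
#'
#' @param patch One-row box tibble.
#' @param gt_boxes Box tibble (possibly empty).
#' @return Proportion in `[0, 1]`.
#' @export
overlap_fraction <- function(patch, gt_boxes) {
  validate_boxes(patch, "patch")
  intersect_union_area(patch, gt_boxes) / box_area(patch)
}

#' Classify a tiled patch
#'
#' Verdicts, in order of precedence:
#' * `skipped` — the patch fails the tissue-relevance test (same rule as the
#'   breast-scan windows): peripheral, tissue-poor tiles are omitted;
#' * `positive` — more than half the patch overlaps ground-truth boxes;
#' * `negative` — less than 10% overlaps;
#' * `ignored` — overlap in `[0.1, 0.5]`, endpoints included; such ambiguous
#'   patches are excluded from training.
#'
#' Threshold comparisons are integer-exact: a patch at exactly 10% or 50%
#' overlap is ignored.
#'
#' @param patch One-row box tibble (position within the image).
#' @param patch_pixels Numeric matrix of the patch content.
#' @param gt_boxes Box tibble of lesion annotations.
#' @param params A [scan_params()]; supplies the tissue-relevance rule.
#' @return One of `"positive"`, `"negative"`, `"ignored"`, `"skipped"`.
#' @export
classify_patch <- function(patch, patch_pixels, gt_boxes,
                           params = scan_params()) {
  frac_bright <- mean(patch_pixels > params$background_cutoff)
  if (!window_relevant(frac_bright, params)) return("skipped")
  inter <- intersect_union_area(patch, gt_boxes)
  area <- box_area(patch)
  if (2L * inter > area) return("positive")
  if (10L * inter < area) return("negative")
  "ignored"
}

#' Build the patch training set for one curriculum stage
#'
#' Tiles every strong-tier case at the given patch size, classifies each
#' patch, and keeps positive and negative samples only. Weak-tier cases
#' contribute nothing here — their boxes are withheld by definition.
#' Negatives are mined both from the normal tissue of positive cases and
#' from negative cases, then down-sampled to the requested
#' negative:positive ratio by a seeded draw.
#'
#' @param cases Preprocessed cohort tibble; only rows with `tier == "strong"`
#'   are used.
#' @param spec A [patch_spec()].
#' @param params A [scan_params()] for the skip rule.
#' @param balance Negative:positive ratio (default 1), or `Inf` to keep all
#'   negatives.
#' @param seed RNG seed for the negative subsample.
#' @return Tibble of patch samples: `case_id`, patch box columns, `pixels`
#'   list-column, `label`, `overlap_fraction`.
#' @export
build_patch_dataset <- function(cases, spec, params = scan_params(),
                                balance = 1, seed = 1L) {
  strong <- filter(cases, .data$tier == "strong")
  out <- vector("list", nrow(strong))
  for (i in seq_len(nrow(strong))) {
    img <- strong$image[[i]]
    gt <- strong$boxes[[i]]
    grid <- tile(nrow(img), spec)
    rows <- vector("list", nrow(grid))
    for (j in seq_len(nrow(grid))) {
      p <- grid[j, ]
      px <- img[(p$y0 + 1):p$y1, (p$x0 + 1):p$x1, drop = FALSE]
      verdict <- classify_patch(p, px, gt, params)
      if (verdict %in% c("positive", "negative")) {
        rows[[j]] <- tibble(
          case_id = paste(strong$patient_id[i], strong$laterality[i],
                          strong$view[i], sep = "_"),
          x0 = p$x0, y0 = p$y0, x1 = p$x1, y1 = p$y1,
          pixels = list(px), label = verdict,
          overlap_fraction = overlap_fraction(p, gt)
        )
      }
    }
    out[[i]] <- bind_rows(rows)
  }
  samples <- bind_rows(out)
  n_pos_cases <- sum(strong$label == "positive")
  if (n_pos_cases > 0 && (nrow(samples) == 0 || !any(samples$label == "positive"))) {
    abort(paste0(
      "no positive patches found across strong positive cases at patch size ",
      spec$patch_size, "; lesions are smaller than resolvable at this size"
    ))
  }
  if (nrow(samples) == 0) return(samples)
  if (is.finite(balance)) {
    pos <- filter(samples, .data$label == "positive")
    neg <- filter(samples, .data$label == "negative")
    keep <- min(nrow(neg), ceiling(balance * max(nrow(pos), 1L)))
    set.seed(as.integer(seed))
    neg <- neg[sample(nrow(neg), keep), ]
    samples <- bind_rows(pos, neg)
  }
  arrange(samples, .data$case_id, .data$y0, .data$x0)
}
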