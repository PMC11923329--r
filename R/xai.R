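#' Grad-CAM saliency map
#'
#' Weights each final-convolution activation channel by the spatial average
#' of the target-class logit's gradient with respect to that channel,
#' rectifies the weighted sum, bilinearly upsamples it to the input size,
#' and min-max normalizes to `[0, 1]`. An all-zero raw map (an uninformative
#' model) is returned as all zeros with the `degenerate` attribute set.
#'
#' @param model A `curri_backbone`.
#' @param image Square numeric matrix (valid network input).
#' @param target_class 1 (negative) or 2 (positive/cancer); default 2.
#' @return Numeric matrix, same size as `image`, in `[0, 1]`; attribute
#'   `degenerate` is `TRUE` for an all-zero map.
#' @export
grad_cam <- function(model, image, target_class = 2L) {
  fca <- final_conv_activations(model, image)
  acts <- fca$activations
  grads <- fca$grad(target_class)
  alpha <- apply(grads, 3, mean)
  raw <- matrix(0, dim(acts)[1], dim(acts)[2])
  for (c in seq_along(alpha)) raw <- raw + alpha[c] * acts[, , c]
  raw[raw < 0] <- 0
  if (all(raw == 0)) {
    out <- matrix(0, nrow(image), ncol(image))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  up <- if (nrow(raw) == nrow(image)) raw else {
    as.matrix(EBImage::resize(raw, w = nrow(image), h = ncol(image),
                              filter = "bilinear"))
  }
  up <- up - min(up)
  out <- up / max(up)
  attr(out, "degenerate") <- FALSE
  out
}

#' Select the top-valued saliency pixels
#'
#' Marks the `budget` highest-valued pixels of a saliency map. Ties at the
#' cut value are broken in row-major order (left-to-right within a row, top
#' row first). A budget at or above the pixel count selects everything; a
#' degenerate all-zero map yields an empty mask.
#'
#' @param saliency Numeric matrix in `[0, 1]`.
#' @param budget Number of pixels to select (>= 1).
#' @return Logical matrix of the same size; attribute `degenerate` mirrors
#'   the saliency's flag.
#' @export
top_pixel_mask <- function(saliency, budget) {
  if (budget < 1) abort("budget must be >= 1")
  mask <- matrix(FALSE, nrow(saliency), ncol(saliency))
  if (isTRUE(attr(saliency, "degenerate")) || all(saliency == 0)) {
    attr(mask, "degenerate") <- TRUE
    return(mask)
  }
  n <- length(saliency)
  budget <- min(budget, n)
  # row-major rank as tie-break: matrices are column-major, so order by
  # value desc, then row-major linear index asc
  rm_index <- as.vector(t(matrix(seq_len(n), nrow(saliency), ncol(saliency))))
  rm_rank <- integer(n)
  rm_rank[rm_index] <- seq_len(n)
  ord <- order(-as.vector(saliency), rm_rank)
  mask[ord[seq_len(budget)]] <- TRUE
  attr(mask, "degenerate") <- FALSE
  mask
}

#' Ground-truth overlap ratio
#'
#' The explainability score: 100 times the number of selected saliency
#' pixels that fall inside the rasterized union of the ground-truth boxes,
#' divided by the total ground-truth pixel count. 100 indicates excellent
#' explainability (the map's top pixels cover the lesions), 0 the worst.
#' Defined only for cancer cases — empty `gt_boxes` is an error.
#'
#' @param mask Logical matrix from [top_pixel_mask()].
#' @param gt_boxes Non-empty box tibble.
#' @return Tibble with `ratio` (percent), `gt_pixel_count`,
#'   `overlap_pixel_count`.
#' @export
overlap_ratio <- function(mask, gt_boxes) {
  if (is.null(gt_boxes) || nrow(gt_boxes) == 0) {
    abort("overlap ratio is undefined for cases without ground-truth boxes")
  }
  gt <- rasterize_boxes(gt_boxes, nrow(mask), ncol(mask))
  gt_n <- sum(gt)
  ov <- sum(mask & gt)
  tibble(ratio = 100 * ov / gt_n, gt_pixel_count = gt_n,
         overlap_pixel_count = ov)
}

#' Cohort-level explainability score
#'
#' Computes the ground-truth overlap ratio for every annotated positive view
#' (Grad-CAM, top-pixel selection, overlap against the boxes), averages the
#' views of each breast, and summarizes over cases. The top-pixel budget
#' defaults to each view's own ground-truth pixel count, so a ratio of 100
#' is exactly attainable; `budget = "top5pct"` selects the top 5% of pixels
#' instead.
#'
#' @param model A `curri_backbone`.
#' @param cases Preprocessed cohort tibble; only positive views with boxes
#'   are scored.
#' @param budget `"gt"` (default) or `"top5pct"`.
#' @return List with `per_case` tibble (one row per breast) and `summary`
#'   (mean, sd over breasts).
#' @export
cohort_overlap <- function(model, cases, budget = c("gt", "top5pct")) {
  budget <- match.arg(budget)
  pos <- filter(cases, .data$label == "positive",
                purrr::map_int(.data$boxes, nrow) > 0)
  if (nrow(pos) == 0) abort("no cancer cases with boxes to score")
  ratios <- purrr::map2_dbl(pos$image, pos$boxes, function(img, gt) {
    sal <- grad_cam(model, img, target_class = 2L)
    b <- switch(budget,
      gt = sum(rasterize_boxes(gt, nrow(img), ncol(img))),
      top5pct = ceiling(0.05 * length(img))
    )
    overlap_ratio(top_pixel_mask(sal, b), gt)$ratio
  })
  per_case <- pos |>
    mutate(ratio = ratios) |>
    group_by(.data$patient_id, .data$laterality) |>
    summarise(ratio = mean(.data$ratio), .groups = "drop")
  list(per_case = per_case, summary = summarize_runs(per_case$ratio))
}
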