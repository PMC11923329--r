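#' Parameters of the patch-based breast-region scan
#'
#' The cropper slides a square window over the mammogram and keeps windows
#' that contain enough tissue. A window is *relevant* when the fraction of
#' its pixels brighter than `background_cutoff` exceeds `black_threshold`
#' (the default reading of a "black threshold of 30%": a window is discarded
#' when 70% or more of it is empty zero-pixel area). Set
#' `threshold_on = "black"` for the complementary reading, under which a
#' window is discarded as soon as 30% of it is black.
#'
#' @param scan_patch_size Window side in pixels.
#' @param scan_stride Window step in pixels; must not exceed the window side.
#' @param black_threshold Proportion in (0, 1).
#' @param background_cutoff Intensity on `[0, 1]` below which a pixel counts
#'   as background.
#' @param threshold_on `"nonblack"` (default) or `"black"`; see Description.
#' @return A validated `scan_params` list.
#' @export
scan_params <- function(scan_patch_size = 400L, scan_stride = 80L,
                        black_threshold = 0.30, background_cutoff = 0.02,
                        threshold_on = c("nonblack", "black")) {
  threshold_on <- match.arg(threshold_on)
  p <- structure(list(
    scan_patch_size = as.integer(scan_patch_size),
    scan_stride = as.integer(scan_stride),
    black_threshold = black_threshold,
    background_cutoff = background_cutoff,
    threshold_on = threshold_on
  ), class = "scan_params")
  if (p$scan_stride > p$scan_patch_size) abort("stride must be <= patch size")
  if (p$scan_stride < 1) abort("stride must be >= 1")
  if (p$black_threshold <= 0 || p$black_threshold >= 1) {
    abort("black_threshold must lie in (0, 1)")
  }
  p
}

# 0-based window start positions along an axis of length n: a regular grid
# plus a final position flush to the far edge when the grid falls short.
grid_starts <- function(n, size, stride) {
  if (n <= size) return(0L)
  starts <- seq(0L, n - size, by = stride)
  if (starts[length(starts)] != n - size) starts <- c(starts, n - size)
  as.integer(starts)
}

# Is a window with this bright-pixel fraction relevant?
window_relevant <- function(frac_bright, params) {
  if (params$threshold_on == "nonblack") {
    frac_bright > params$black_threshold
  } else {
    frac_bright > 1 - params$black_threshold
  }
}

# Bright-pixel fraction of every scan window via an integral image; rows of
# the result index y-starts, columns x-starts.
window_bright_fractions <- function(image, params) {
  ys <- grid_starts(nrow(image), params$scan_patch_size, params$scan_stride)
  xs <- grid_starts(ncol(image), params$scan_patch_size, params$scan_stride)
  ps <- min(params$scan_patch_size, nrow(image), ncol(image))
  bin <- image > params$background_cutoff
  ii <- rbind(0, cbind(0, apply(apply(bin, 2, cumsum), 1, cumsum) |> t()))
  # ii is (h+1) x (w+1); sum over [y0,y1) x [x0,x1) =
  #   ii[y1+1, x1+1] - ii[y0+1, x1+1] - ii[y1+1, x0+1] + ii[y0+1, x0+1]
  win_h <- min(params$scan_patch_size, nrow(image))
  win_w <- min(params$scan_patch_size, ncol(image))
  frac <- matrix(0, length(ys), length(xs))
  for (i in seq_along(ys)) {
    y0 <- ys[i]; y1 <- y0 + win_h
    for (j in seq_along(xs)) {
      x0 <- xs[j]; x1 <- x0 + win_w
      s <- ii[y1 + 1, x1 + 1] - ii[y0 + 1, x1 + 1] -
        ii[y1 + 1, x0 + 1] + ii[y0 + 1, x0 + 1]
      frac[i, j] <- s / (win_h * win_w)
    }
  }
  list(frac = frac, ys = ys, xs = xs, win_h = win_h, win_w = win_w)
}

#' Locate the breast region by patch-based scanning
#'
#' Slides a `scan_patch_size` window at `scan_stride` over the mammogram,
#' marks tissue-relevant windows, and returns the tight bounding box of the
#' largest 8-connected component of relevant windows — the most significant
#' section of breast tissue. Components are compared by relevant-window
#' count, ties broken by covered pixel area, then by top-left-most bounding
#' box. Images no larger than the window in both dimensions are returned
#' whole.
#'
#' @param image Numeric matrix with values in `[0, 1]` (rows = y, cols = x).
#' @param params A [scan_params()].
#' @return A one-row box tibble, clipped to the image bounds.
#' @export
scan_breast_region <- function(image, params = scan_params()) {
  h <- nrow(image); w <- ncol(image)
  if (h <= params$scan_patch_size && w <= params$scan_patch_size) {
    if (!any(image > params$background_cutoff)) {
      abort("empty image: no pixel above background cutoff",
            class = "curripatch_empty_image")
    }
    return(boxes(0L, 0L, w, h))
  }
  sc <- window_bright_fractions(image, params)
  rel <- window_relevant(sc$frac, params)
  if (!any(rel)) {
    abort("empty image: no relevant window found by the breast scan",
          class = "curripatch_empty_image")
  }
  labels <- label_components_8(rel)
  comp_ids <- setdiff(sort(unique(as.vector(labels))), 0L)
  best <- NULL
  for (id in comp_ids) {
    cells <- which(labels == id, arr.ind = TRUE)
    bx <- component_pixel_box(cells, sc)
    cand <- list(id = id, count = nrow(cells), box = bx,
                 area = component_pixel_area(cells, sc, h, w))
    if (is.null(best) || component_better(cand, best)) best <- cand
  }
  b <- best$box
  boxes(max(b[1], 0L), max(b[2], 0L), min(b[3], w), min(b[4], h))
}

component_pixel_box <- function(cells, sc) {
  y0 <- min(sc$ys[cells[, 1]]); x0 <- min(sc$xs[cells[, 2]])
  y1 <- max(sc$ys[cells[, 1]]) + sc$win_h
  x1 <- max(sc$xs[cells[, 2]]) + sc$win_w
  c(x0, y0, x1, y1)
}

# Pixel area covered by the union of a component's window footprints.
component_pixel_area <- function(cells, sc, h, w) {
  bx <- component_pixel_box(cells, sc)
  sub_h <- bx[4] - bx[2]; sub_w <- bx[3] - bx[1]
  m <- matrix(FALSE, sub_h, sub_w)
  for (k in seq_len(nrow(cells))) {
    ys <- sc$ys[cells[k, 1]] - bx[2]; xs <- sc$xs[cells[k, 2]] - bx[1]
    m[(ys + 1):(ys + sc$win_h), (xs + 1):(xs + sc$win_w)] <- TRUE
  }
  sum(m)
}

component_better <- function(a, b) {
  if (a$count != b$count) return(a$count > b$count)
  if (a$area != b$area) return(a$area > b$area)
  if (a$box[2] != b$box[2]) return(a$box[2] < b$box[2])
  a$box[1] < b$box[1]
}

#' Expand a region to cover all ground-truth boxes
#'
#' Quality-control step: the crop must not discard annotated lesions. Returns
#' the minimal box containing the region and every ground-truth box.
#'
#' @param region One-row box tibble.
#' @param gt_boxes Box tibble (possibly empty).
#' @return One-row box tibble.
#' @export
expand_to_cover <- function(region, gt_boxes) {
  validate_boxes(region, "region")
  if (is.null(gt_boxes) || nrow(gt_boxes) == 0) return(region)
  union_extent(region, gt_boxes)
}

#' Crop to a region and zero-pad to a square
#'
#' Crops the image to `region`, then pads the shorter dimension with zeros,
#' split symmetrically; an odd deficit puts the smaller pad first (left or
#' top). Boxes are shifted by the crop and pad offsets; no box pixel is lost.
#'
#' @param image Numeric matrix.
#' @param region One-row box tibble within the image.
#' @param gt_boxes Box tibble to co-transform.
#' @return List with `image` (square matrix), `boxes`, and integer offsets
#'   `crop_x0`, `crop_y0`, `pad_left`, `pad_top`.
#' @export
crop_pad_square <- function(image, region, gt_boxes = empty_boxes()) {
  validate_boxes(region, "region")
  if (region$x0 < 0 || region$y0 < 0 ||
      region$x1 > ncol(image) || region$y1 > nrow(image)) {
    abort("region must lie within the image")
  }
  cropped <- image[(region$y0 + 1):region$y1, (region$x0 + 1):region$x1,
                   drop = FALSE]
  h <- nrow(cropped); w <- ncol(cropped)
  side <- max(h, w)
  pad_left <- (side - w) %/% 2L
  pad_top <- (side - h) %/% 2L
  out <- matrix(0, side, side)
  out[(pad_top + 1):(pad_top + h), (pad_left + 1):(pad_left + w)] <- cropped
  b <- shift_boxes(gt_boxes, -region$x0 + pad_left, -region$y0 + pad_top)
  list(image = out, boxes = b,
       crop_x0 = region$x0, crop_y0 = region$y0,
       pad_left = as.integer(pad_left), pad_top = as.integer(pad_top))
}

#' Resize a square image to the network input size
#'
#' Bilinear resampling to `target_size` x `target_size`. Box coordinates are
#' scaled by `target_size / input_size` and rounded half away from zero, so a
#' full-frame box maps to the full output frame. The returned transform
#' record (crop offset, pad offsets, scale) is sufficient to map output boxes
#' back to native coordinates within one pixel per coordinate.
#'
#' @param padded Output of [crop_pad_square()], or a list with `image`,
#'   `boxes` and offsets.
#' @param target_size Output side in pixels (1024 by default).
#' @return A `crop_result`: list with square `image`, transformed `boxes`,
#'   and `transform`.
#' @export
resize_square <- function(padded, target_size = 1024L) {
  img <- padded$image
  if (nrow(img) != ncol(img)) abort("resize_square expects a square input")
  input_size <- nrow(img)
  scale <- target_size / input_size
  resized <- if (input_size == target_size) img else {
    as.matrix(EBImage::resize(img, w = target_size, h = target_size,
                              filter = "bilinear"))
  }
  structure(list(
    image = pmin(pmax(resized, 0), 1),
    boxes = scale_boxes(padded$boxes, scale),
    transform = list(
      crop_x0 = padded$crop_x0 %||% 0L, crop_y0 = padded$crop_y0 %||% 0L,
      pad_left = padded$pad_left %||% 0L, pad_top = padded$pad_top %||% 0L,
      scale = scale
    )
  ), class = "crop_result")
}

#' Map preprocessed-frame boxes back to native coordinates
#'
#' Inverts the crop/pad/resize transform recorded in a `crop_result`.
#'
#' @param b Box tibble in the preprocessed frame.
#' @param transform The `transform` element of a `crop_result`.
#' @return Box tibble in native image coordinates.
#' @export
invert_boxes <- function(b, transform) {
  if (nrow(b) == 0) return(b)
  mutate(b,
    across(c("x0", "x1"), ~ as.integer(round_half_away(
      .x / transform$scale - transform$pad_left + transform$crop_x0))),
    across(c("y0", "y1"), ~ as.integer(round_half_away(
      .x / transform$scale - transform$pad_top + transform$crop_y0)))
  )
}

#' Preprocess one view: scan, crop, pad, resize
#'
#' The full preprocessing chain: locate the breast region by window scanning,
#' expand it so no ground-truth box is excluded, crop, zero-pad to a square,
#' and resample to the network input size, co-transforming the boxes.
#'
#' @param image Numeric matrix in `[0, 1]`.
#' @param gt_boxes Box tibble of lesion annotations (possibly empty).
#' @param params A [scan_params()].
#' @param target_size Output side in pixels.
#' @return A `crop_result` (see [resize_square()]).
#' @export
preprocess_view <- function(image, gt_boxes = empty_boxes(),
                            params = scan_params(), target_size = 1024L) {
  region <- scan_breast_region(image, params)
  region <- expand_to_cover(region, gt_boxes)
  region <- boxes(max(region$x0, 0L), max(region$y0, 0L),
                  min(region$x1, ncol(image)), min(region$y1, nrow(image)))
  padded <- crop_pad_square(image, region, gt_boxes)
  resize_square(padded, target_size)
}

#' Preprocess every view of a cohort
#'
#' Applies [preprocess_view()] to each row of a cohort tibble, replacing the
#' `image` and `boxes` columns with their preprocessed versions and adding a
#' `transform` list-column.
#'
#' @param cases Cohort tibble ([generate_cohort()]).
#' @param params A [scan_params()].
#' @param target_size Output side in pixels.
#' @return The cohort tibble in the preprocessed frame.
#' @export
preprocess_cohort <- function(cases, params = scan_params(),
                              target_size = 1024L) {
  res <- purrr::map2(cases$image, cases$boxes,
                     ~ preprocess_view(.x, .y, params, target_size))
  cases$image <- purrr::map(res, "image")
  cases$boxes <- purrr::map(res, "boxes")
  cases$transform <- purrr::map(res, "transform")
  cases
}
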