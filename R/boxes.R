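#' Axis-aligned pixel boxes
#'
#' Boxes are the unit of lesion annotation, cropping and patching. A box set is
#' a tibble with integer columns `x0, y0, x1, y1` in 0-based, half-open pixel
#' coordinates: the box covers columns `[x0, x1)` and rows `[y0, y1)`, with
#' `x` indexing columns and `y` indexing rows. A valid box has `x1 > x0` and
#' `y1 > y0`, hence positive area.
#'
#' @param x0,y0,x1,y1 Integer pixel coordinates (vectors of equal length).
#' @return A tibble with one row per box.
#' @examples
#' boxes(x0 = 10, y0 = 20, x1 = 50, y1 = 80)
#' @export
boxes <- function(x0 = integer(), y0 = integer(), x1 = integer(), y1 = integer()) {
  out <- tibble(
    x0 = as.integer(x0), y0 = as.integer(y0),
    x1 = as.integer(x1), y1 = as.integer(y1)
  )
  validate_boxes(out)
  out
}

validate_boxes <- function(b, where = "boxes") {
  if (!is.data.frame(b)) abort(paste0(where, " must be a data frame"))
  need <- c("x0", "y0", "x1", "y1")
  if (!all(need %in% names(b))) {
    abort(paste0(where, " must have columns x0, y0, x1, y1"))
  }
  if (nrow(b) > 0 && any(b$x1 <= b$x0 | b$y1 <= b$y0)) {
    abort(paste0(where, " contains a degenerate box (x1 <= x0 or y1 <= y0)"))
  }
  invisible(b)
}

empty_boxes <- function() boxes()

box_area <- function(b) (b$x1 - b$x0) * (b$y1 - b$y0)

#' Rasterize a set of boxes to a logical mask
#'
#' Marks every pixel covered by the union of the boxes. Pixel `(x, y)` in
#' 0-based coordinates maps to matrix entry `[y + 1, x + 1]` (row = y,
#' col = x). Boxes are clipped to the image extent.
#'
#' @param gt_boxes Tibble of boxes (see [boxes()]).
#' @param height,width Image extent in pixels.
#' @return Logical `height x width` matrix; union, not multiplicity.
#' @export
rasterize_boxes <- function(gt_boxes, height, width) {
  mask <- matrix(FALSE, nrow = height, ncol = width)
  if (is.null(gt_boxes) || nrow(gt_boxes) == 0) return(mask)
  for (i in seq_len(nrow(gt_boxes))) {
    x0 <- max(gt_boxes$x0[i], 0L); x1 <- min(gt_boxes$x1[i], width)
    y0 <- max(gt_boxes$y0[i], 0L); y1 <- min(gt_boxes$y1[i], height)
    if (x1 > x0 && y1 > y0) mask[(y0 + 1L):y1, (x0 + 1L):x1] <- TRUE
  }
  mask
}

# Shift all boxes by (dx, dy); used by crop/pad co-transforms.
shift_boxes <- function(b, dx, dy) {
  if (nrow(b) == 0) return(b)
  mutate(b,
    x0 = .data$x0 + as.integer(dx), x1 = .data$x1 + as.integer(dx),
    y0 = .data$y0 + as.integer(dy), y1 = .data$y1 + as.integer(dy)
  )
}

# Round half away from zero (base::round is round-half-even).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# Scale box coordinates by a factor, rounding half away from zero.
scale_boxes <- function(b, scale) {
  if (nrow(b) == 0) return(b)
  mutate(b, across(c("x0", "y0", "x1", "y1"),
                   ~ as.integer(round_half_away(.x * scale))))
}

# Minimal box covering two box sets (used by expand_to_cover).
union_extent <- function(a, b) {
  both <- bind_rows(a, b)
  boxes(min(both$x0), min(both$y0), max(both$x1), max(both$y1))
}

# Exact intersection area (in pixels) between one patch box and the union of
# gt boxes, by coordinate compression on integer boundaries. Integer-exact.
intersect_union_area <- function(patch, gt_boxes) {
  if (is.null(gt_boxes) || nrow(gt_boxes) == 0) return(0L)
  cx0 <- pmax(gt_boxes$x0, patch$x0); cx1 <- pmin(gt_boxes$x1, patch$x1)
  cy0 <- pmax(gt_boxes$y0, patch$y0); cy1 <- pmin(gt_boxes$y1, patch$y1)
  keep <- cx1 > cx0 & cy1 > cy0
  if (!any(keep)) return(0L)
  cx0 <- cx0[keep]; cx1 <- cx1[keep]; cy0 <- cy0[keep]; cy1 <- cy1[keep]
  xs <- sort(unique(c(cx0, cx1)))
  ys <- sort(unique(c(cy0, cy1)))
  area <- 0L
  for (i in seq_len(length(xs) - 1L)) {
    for (j in seq_len(length(ys) - 1L)) {
      covered <- any(cx0 <= xs[i] & cx1 >= xs[i + 1L] &
                     cy0 <= ys[j] & cy1 >= ys[j + 1L])
      if (covered) {
        area <- area + (xs[i + 1L] - xs[i]) * (ys[j + 1L] - ys[j])
      }
    }
  }
  as.integer(area)
}
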