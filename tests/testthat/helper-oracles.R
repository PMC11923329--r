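# Independent brute-force oracles. These deliberately share no code with the
# package internals they check: per-pixel rasterization instead of coordinate
# compression, per-window extraction instead of integral images, igraph
# instead of the package's BFS labeler, finite differences instead of
# backprop.

# --- per-pixel overlap oracle -----------------------------------------------

# Fraction of a patch covered by the union of gt boxes, counted pixel by
# pixel on a logical canvas.
oracle_overlap_fraction <- function(patch, gt_boxes) {
  w <- max(patch$x1, if (nrow(gt_boxes)) max(gt_boxes$x1) else 0)
  h <- max(patch$y1, if (nrow(gt_boxes)) max(gt_boxes$y1) else 0)
  canvas <- matrix(FALSE, h, w)
  for (i in seq_len(nrow(gt_boxes))) {
    canvas[(gt_boxes$y0[i] + 1):gt_boxes$y1[i],
           (gt_boxes$x0[i] + 1):gt_boxes$x1[i]] <- TRUE
  }
  sub <- canvas[(patch$y0 + 1):patch$y1, (patch$x0 + 1):patch$x1]
  sum(sub) / length(sub)
}

# Integer pixel count of the patch/union intersection (for exact threshold
# comparisons).
oracle_overlap_count <- function(patch, gt_boxes) {
  as.integer(round(oracle_overlap_fraction(patch, gt_boxes) *
                     (patch$x1 - patch$x0) * (patch$y1 - patch$y0)))
}

# --- exhaustive window-scan oracle ------------------------------------------

# Recomputes the breast-region box by extracting every scan window,
# measuring its bright fraction directly, labeling relevant windows with
# igraph (8-connectivity on the window grid), and applying the documented
# selection rule (window count, then covered pixel area, then top-left).
oracle_scan_region <- function(image, params) {
  h <- nrow(image); w <- ncol(image)
  ps <- params$scan_patch_size
  starts <- function(n) {
    if (n <= ps) return(0L)
    s <- seq(0L, n - ps, by = params$scan_stride)
    if (s[length(s)] != n - ps) s <- c(s, n - ps)
    s
  }
  ys <- starts(h); xs <- starts(w)
  win_h <- min(ps, h); win_w <- min(ps, w)
  rel <- matrix(FALSE, length(ys), length(xs))
  for (i in seq_along(ys)) {
    for (j in seq_along(xs)) {
      win <- image[(ys[i] + 1):(ys[i] + win_h), (xs[j] + 1):(xs[j] + win_w)]
      fb <- mean(win > params$background_cutoff)
      rel[i, j] <- if (params$threshold_on == "nonblack") {
        fb > params$black_threshold
      } else {
        fb > 1 - params$black_threshold
      }
    }
  }
  if (!any(rel)) return(NULL)
  cells <- which(rel, arr.ind = TRUE)
  n <- nrow(cells)
  if (n == 1) {
    comp <- rep(1L, 1)
  } else {
    adj <- outer(seq_len(n), seq_len(n), function(a, b) {
      abs(cells[a, 1] - cells[b, 1]) <= 1 & abs(cells[a, 2] - cells[b, 2]) <= 1
    })
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                             diag = FALSE)
    comp <- igraph::components(g)$membership
  }
  best <- NULL
  for (id in sort(unique(comp))) {
    cc <- cells[comp == id, , drop = FALSE]
    y0 <- min(ys[cc[, 1]]); x0 <- min(xs[cc[, 2]])
    y1 <- max(ys[cc[, 1]]) + win_h; x1 <- max(xs[cc[, 2]]) + win_w
    cover <- matrix(FALSE, h, w)
    for (k in seq_len(nrow(cc))) {
      cover[(ys[cc[k, 1]] + 1):(ys[cc[k, 1]] + win_h),
            (xs[cc[k, 2]] + 1):(xs[cc[k, 2]] + win_w)] <- TRUE
    }
    cand <- list(count = nrow(cc), area = sum(cover),
                 box = c(x0, y0, min(x1, w), min(y1, h)))
    if (is.null(best)) best <- cand
    else {
      better <- cand$count > best$count ||
        (cand$count == best$count && cand$area > best$area) ||
        (cand$count == best$count && cand$area == best$area &&
           (cand$box[2] < best$box[2] ||
              (cand$box[2] == best$box[2] && cand$box[1] < best$box[1])))
      if (better) best <- cand
    }
  }
  best$box
}

# Random multi-blob phantom for the scan oracle suite: black canvas with a
# few bright rectangles and discs.
random_blob_image <- function(h, w, n_blobs = sample(1:3, 1)) {
  img <- matrix(0, h, w)
  for (b in seq_len(n_blobs)) {
    bw <- sample(floor(w / 6):floor(w / 2), 1)
    bh <- sample(floor(h / 6):floor(h / 2), 1)
    x0 <- sample(0:(w - bw), 1); y0 <- sample(0:(h - bh), 1)
    img[(y0 + 1):(y0 + bh), (x0 + 1):(x0 + bw)] <- runif(1, 0.4, 0.9)
  }
  img
}

# --- misc helpers -----------------------------------------------------------

resample1 <- function(v) v[sample.int(length(v), 1L)]

random_boxes <- function(n, extent, min_side = 2L) {
  if (n == 0) return(boxes())
  x0 <- sample(0:(extent - min_side), n, replace = TRUE)
  y0 <- sample(0:(extent - min_side), n, replace = TRUE)
  x1 <- purrr::map_int(x0, ~ resample1((.x + min_side):extent))
  y1 <- purrr::map_int(y0, ~ resample1((.x + min_side):extent))
  boxes(x0, y0, x1, y1)
}

# Tiny two-class patch set that is linearly separable by brightness.
separable_patches <- function(n_per_class = 8, side = 16, seed = 1) {
  set.seed(seed)
  bright <- purrr::map(seq_len(n_per_class),
                       ~ matrix(runif(side^2, 0.7, 0.9), side, side))
  dark <- purrr::map(seq_len(n_per_class),
                     ~ matrix(runif(side^2, 0.0, 0.15), side, side))
  tibble::tibble(
    pixels = c(bright, dark),
    label = rep(c("positive", "negative"), each = n_per_class)
  )
}

# Hand-built toy network: one conv block (no pool) whose 3x3 kernels are
# scaled identities (center tap s_c), plus a fixed linear head. Activations
# are then s_c * input for positive inputs, which makes the Grad-CAM closed
# form hand-derivable.
toy_identity_model <- function(scales = c(1, 0.5, 2),
                               headW = matrix(c(0.3, -0.2, 0.7,
                                                0.1, 0.4, -0.1),
                                              2, 3, byrow = TRUE)) {
  cfg <- backbone_config("tiny", channels = length(scales))
  W <- matrix(0, length(scales), 9)
  W[, 5] <- scales  # column 5 is the center tap (kx = 1, ky = 1)
  model <- init_backbone(cfg, seed = 1)
  model$conv[[1]]$W <- W
  model$conv[[1]]$b <- numeric(length(scales))
  model$head$W <- headW
  model$head$b <- c(0.05, -0.05)
  model
}
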