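test_that("grad_cam on the identity toy net matches the hand-derived form", {
  m <- toy_identity_model(scales = c(1, 0.5, 2))
  x <- matrix(runif(16^2, 0.1, 0.9), 16, 16)
  hw <- 16^2
  # activations are s_c * x; channel weights are W[2, c] / HW, so the raw
  # map is ReLU(sum_c W[2, c] * s_c / HW * x); min-max normalize to compare
  coef <- sum(m$head$W[2, ] * c(1, 0.5, 2)) / hw
  raw <- pmax(coef * x, 0)
  want <- (raw - min(raw)) / (max(raw) - min(raw))
  got <- grad_cam(m, x, target_class = 2L)
  expect_equal(matrix(got, 16, 16), want, tolerance = 1e-10)
  expect_false(attr(got, "degenerate"))
  expect_equal(min(got), 0)
  expect_equal(max(got), 1)
})

test_that("a head that ignores all channels yields a flagged all-zero map", {
  m <- init_backbone(backbone_config("tiny"), seed = 1)  # zero head
  sal <- grad_cam(m, matrix(runif(32^2), 32, 32))
  expect_true(attr(sal, "degenerate"))
  expect_true(all(sal == 0))
  mask <- top_pixel_mask(sal, 10)
  expect_true(attr(mask, "degenerate"))
  expect_equal(sum(mask), 0)
})

test_that("non-degenerate maps are min-max normalized across model seeds", {
  for (seed in 1:3) {
    m <- init_backbone(backbone_config("tiny"), seed = seed)
    m$head$W <- matrix(rnorm(64, 0, 0.5), 2, 32)
    sal <- grad_cam(m, matrix(runif(64^2, 0.2, 0.8), 64, 64))
    if (!attr(sal, "degenerate")) {
      expect_equal(min(sal), 0)
      expect_equal(max(sal), 1)
      expect_equal(dim(sal), c(64, 64))
    }
  }
})

test_that("top_pixel_mask selects exactly the budget with row-major ties", {
  sal <- matrix(0, 6, 6)
  sal[2, c(2, 4)] <- 1
  sal[5, 3] <- 1
  attr(sal, "degenerate") <- FALSE
  mask <- top_pixel_mask(sal, 3)
  expect_identical(unname(which(mask)), unname(which(sal == 1)))
  # budget >= total selects everything
  expect_equal(sum(top_pixel_mask(sal, 100)), 36)
  # uniform saliency: first pixels in row-major order win
  uni <- matrix(0.5, 4, 4)
  m5 <- top_pixel_mask(uni, 5)
  expect_equal(sum(m5), 5)
  expect_true(all(m5[1, ]))       # full first row
  expect_true(m5[2, 1])           # then the start of the second row
  expect_equal(sum(m5[2:4, ]), 1)
})

test_that("overlap ratio hits the documented extremes and brute force", {
  gt <- boxes(10L, 10L, 20L, 20L)
  full <- rasterize_boxes(gt, 40L, 40L)
  expect_equal(overlap_ratio(full, gt)$ratio, 100)
  disjoint <- rasterize_boxes(boxes(25L, 25L, 35L, 35L), 40L, 40L)
  expect_equal(overlap_ratio(disjoint, gt)$ratio, 0)
  # half coverage, verified per pixel
  half <- matrix(FALSE, 40, 40)
  half[11:20, 11:15] <- TRUE
  r <- overlap_ratio(half, gt)
  expect_equal(r$ratio, 50)
  expect_equal(r$overlap_pixel_count, sum(half & full))
  expect_equal(r$gt_pixel_count, 100)
  expect_error(overlap_ratio(full, boxes()), "without ground-truth")
})

test_that("overlap ratio equals brute force on random masks and boxes", {
  set.seed(55)
  for (rep in 1:40) {
    gt <- random_boxes(sample(1:3, 1), 48L)
    mask <- matrix(runif(64^2) < 0.3, 64, 64)
    gt_px <- rasterize_boxes(gt, 64L, 64L)
    want <- 100 * sum(mask & gt_px) / sum(gt_px)
    expect_equal(overlap_ratio(mask, gt)$ratio, want)
  }
})

test_that("overlap ratio is monotone non-decreasing in the budget", {
  set.seed(66)
  sal <- matrix(runif(32^2), 32, 32)
  gt <- boxes(5L, 5L, 20L, 25L)
  ratios <- purrr::map_dbl(c(10, 50, 200, 600, 1024),
                           ~ overlap_ratio(top_pixel_mask(sal, .x), gt)$ratio)
  expect_true(all(diff(ratios) >= 0))
  expect_true(all(ratios >= 0 & ratios <= 100))
})

test_that("random saliency at a gt-sized budget scores about 100 x area fraction", {
  set.seed(77)
  side <- 40L
  gt <- boxes(8L, 8L, 24L, 28L)  # 16 x 20 = 320 of 1600 pixels, f = 0.2
  f <- 320 / side^2
  ratios <- replicate(1000, {
    sal <- matrix(runif(side^2), side, side)
    overlap_ratio(top_pixel_mask(sal, 320L), gt)$ratio
  })
  expect_equal(mean(ratios), 100 * f, tolerance = 3 / (100 * f))
})

test_that("cohort_overlap scores annotated positives and averages per breast", {
  cfg <- phantom_config(image_height = 96L, image_width = 80L,
                        n_patients = 4L, lesion_radius_range = c(12L, 16L),
                        lesion_count_range = c(1L, 1L), seed = 19L)
  pp <- preprocess_cohort(generate_cohort(cfg),
                          scan_params(scan_patch_size = 32L,
                                      scan_stride = 16L), 64L)
  m <- init_backbone(backbone_config("tiny"), seed = 3)
  m$head$W <- matrix(rnorm(64, 0, 0.5), 2, 32)
  ov <- cohort_overlap(m, pp)
  expect_equal(nrow(ov$per_case), 2)  # 2 positive patients, 1 breast each
  expect_true(all(ov$per_case$ratio >= 0 & ov$per_case$ratio <= 100))
  expect_true(ov$summary$n == 2)
})
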