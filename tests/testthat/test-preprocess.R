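test_that("uniform bright image scans to the full frame; blank input errors", {
  p <- scan_params(scan_patch_size = 40L, scan_stride = 20L)
  img <- matrix(0.8, 130, 90)
  expect_equal(scan_breast_region(img, p), boxes(0L, 0L, 90L, 130L))
  expect_error(scan_breast_region(matrix(0, 130, 90), p),
               class = "curripatch_empty_image")
  # image no larger than the scan window: returned whole
  expect_equal(scan_breast_region(matrix(0.5, 30, 30), p),
               boxes(0L, 0L, 30L, 30L))
})

test_that("a bright square on black matches the exhaustive window oracle", {
  set.seed(42)
  img <- matrix(0, 2000, 2000)
  img[701:1300, 901:1500] <- 0.7
  got <- scan_breast_region(img, scan_params())
  oracle <- oracle_scan_region(img, scan_params())
  expect_equal(unlist(got, use.names = FALSE), oracle)
  # the returned box must contain the bright square
  expect_true(got$x0 <= 900 && got$x1 >= 1500 &&
                got$y0 <= 700 && got$y1 >= 1300)
})

test_that("raising the black threshold never adds relevant windows", {
  set.seed(7)
  for (rep in 1:10) {
    img <- random_blob_image(300, 260)
    img <- img + matrix(runif(length(img), 0, 0.05), nrow(img))
    fr <- curripatch:::window_bright_fractions(
      img, scan_params(scan_patch_size = 64L, scan_stride = 32L))$frac
    thresholds <- sort(runif(5, 0.05, 0.95))
    sets <- lapply(thresholds, function(t) fr > t)
    for (k in seq_len(length(sets) - 1)) {
      expect_true(all(sets[[k]] | !sets[[k + 1]]))  # set inclusion
    }
  }
})

test_that("expand_to_cover is the minimal cover of region and boxes", {
  region <- boxes(100L, 100L, 300L, 400L)
  expect_identical(expand_to_cover(region, boxes()), region)
  inside <- boxes(150L, 150L, 200L, 200L)
  expect_identical(expand_to_cover(region, inside), region)
  protruding <- boxes(250L, 150L, 310L, 200L)
  expect_equal(expand_to_cover(region, protruding),
               boxes(100L, 100L, 310L, 400L))
})

test_that("crop_pad_square pads symmetrically with the smaller pad first", {
  img <- matrix(runif(1000 * 1200), 1000, 1200)
  sq <- crop_pad_square(img, boxes(100L, 100L, 500L, 500L),
                        boxes(120L, 130L, 200L, 210L))
  expect_equal(dim(sq$image), c(400, 400))
  expect_equal(sq$boxes, boxes(20L, 30L, 100L, 110L))

  # region 800 wide x 1000 tall: width padded 100 each side
  sq2 <- crop_pad_square(img, boxes(0L, 0L, 800L, 1000L))
  expect_equal(dim(sq2$image), c(1000, 1000))
  expect_equal(sq2$pad_left, 100L)
  expect_equal(sq2$pad_top, 0L)

  # odd deficit 801 x 1000: pads split 99 (left) / 100
  sq3 <- crop_pad_square(img, boxes(0L, 0L, 801L, 1000L))
  expect_equal(sq3$pad_left, 99L)
  # pixel content is preserved at the offset
  expect_equal(sq3$image[1:1000, 100:900], img[1:1000, 1:801])
})

test_that("resize_square scales boxes exactly at integer ratios", {
  padded <- list(image = matrix(runif(2048^2 / 16), 512, 512),
                 boxes = boxes(100L, 100L, 300L, 300L),
                 crop_x0 = 0L, crop_y0 = 0L, pad_left = 0L, pad_top = 0L)
  # upscale x2
  up <- resize_square(padded, 1024L)
  expect_equal(up$boxes, boxes(200L, 200L, 600L, 600L))
  expect_equal(dim(up$image), c(1024, 1024))
  # identity
  same <- resize_square(padded, 512L)
  expect_identical(same$boxes, padded$boxes)
  # full-frame box maps to full frame at a non-integer ratio
  padded$boxes <- boxes(0L, 0L, 512L, 512L)
  odd <- resize_square(padded, 1000L)
  expect_equal(odd$boxes, boxes(0L, 0L, 1000L, 1000L))
})

test_that("preprocessing keeps every ground-truth box at positive area", {
  set.seed(31)
  cfg <- phantom_config(image_height = 160L, image_width = 120L,
                        n_patients = 6L, lesion_radius_range = c(12L, 18L),
                        seed = 17L)
  coh <- generate_cohort(cfg)
  pp <- preprocess_cohort(coh, scan_params(scan_patch_size = 48L,
                                           scan_stride = 16L), 128L)
  for (i in seq_len(nrow(pp))) {
    b <- pp$boxes[[i]]
    if (nrow(b) > 0) {
      expect_true(all(b$x1 > b$x0 & b$y1 > b$y0))
      expect_true(all(b$x0 >= 0 & b$y0 >= 0 & b$x1 <= 128 & b$y1 <= 128))
    }
  }
})
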