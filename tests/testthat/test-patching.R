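test_that("tiling counts and flush-edge placement are exact", {
  expect_equal(nrow(tile(1024L, patch_spec(128L))), 64)
  expect_equal(nrow(tile(1024L, patch_spec(512L))), 4)
  g1 <- tile(1024L, patch_spec(1024L))
  expect_equal(g1, boxes(0L, 0L, 1024L, 1024L))
  # 100 with size 40, stride 40: starts 0, 40, then flush 60
  g <- tile(100L, patch_spec(40L))
  expect_equal(sort(unique(g$x0)), c(0L, 40L, 60L))
  expect_equal(nrow(g), 9)
  expect_equal(nrow(dplyr::distinct(g)), nrow(g))
})

test_that("overlap_fraction matches hand values and the union semantics", {
  patch <- boxes(0L, 0L, 100L, 100L)
  expect_equal(overlap_fraction(patch, boxes(0L, 0L, 50L, 100L)), 0.5)
  expect_equal(overlap_fraction(patch, boxes()), 0)
  # two disjoint boxes covering the left 40 columns
  two <- boxes(c(0L, 0L), c(0L, 50L), c(40L, 40L), c(50L, 100L))
  expect_equal(overlap_fraction(patch, two), 0.4)
  expect_equal(overlap_fraction(patch, two),
               oracle_overlap_fraction(patch, two))
  # overlapping gt boxes must not double count
  dup <- boxes(c(0L, 0L), c(0L, 0L), c(40L, 40L), c(100L, 60L))
  expect_equal(overlap_fraction(patch, dup), 0.4)
})

test_that("overlap_fraction equals the per-pixel oracle on random box sets", {
  set.seed(123)
  for (rep in 1:60) {
    patch_side <- sample(c(20L, 32L, 50L), 1)
    x0 <- sample(0:40, 1); y0 <- sample(0:40, 1)
    patch <- boxes(x0, y0, x0 + patch_side, y0 + patch_side)
    gt <- random_boxes(sample(0:4, 1), 90L)
    expect_equal(overlap_fraction(patch, gt),
                 oracle_overlap_fraction(patch, gt))
  }
})

test_that("verdict thresholds are exact at 10% and 50%", {
  tissue <- matrix(0.5, 100, 100)
  patch <- boxes(0L, 0L, 100L, 100L)
  p <- scan_params()
  expect_equal(classify_patch(patch, tissue, boxes(0L, 0L, 50L, 100L), p),
               "ignored")   # exactly 0.5
  expect_equal(classify_patch(patch, tissue, boxes(0L, 0L, 10L, 100L), p),
               "ignored")   # exactly 0.1
  just_over <- boxes(c(0L, 50L), c(0L, 0L), c(50L, 51L), c(100L, 1L))
  expect_equal(classify_patch(patch, tissue, just_over, p), "positive") # 0.5001
  just_under <- boxes(0L, 0L, 10L, 99L)                                 # 0.099
  expect_equal(classify_patch(patch, tissue, just_under, p), "negative")
  expect_equal(classify_patch(patch, tissue, boxes(0L, 0L, 100L, 100L), p),
               "positive")
})

test_that("the skip test precedes labeling and uses the scan relevance rule", {
  patch <- boxes(0L, 0L, 100L, 100L)
  black <- matrix(0, 100, 100)
  black[1:20, 1:20] <- 0.5  # 4% tissue, under the 30% relevance threshold
  expect_equal(classify_patch(patch, black, boxes(0L, 0L, 30L, 30L),
                              scan_params()), "skipped")
})

test_that("every tiled patch gets exactly one verdict and counts partition", {
  set.seed(5)
  img <- matrix(0, 128, 128)
  img[20:110, 10:90] <- 0.6
  img[40:70, 30:60] <- 0.85
  gt <- boxes(29L, 39L, 60L, 70L)
  spec <- patch_spec(32L)
  grid <- tile(128L, spec)
  verdicts <- purrr::map_chr(seq_len(nrow(grid)), function(j) {
    p <- grid[j, ]
    classify_patch(p, img[(p$y0 + 1):p$y1, (p$x0 + 1):p$x1], gt,
                   scan_params())
  })
  expect_equal(length(verdicts), nrow(grid))
  expect_true(all(verdicts %in% c("positive", "negative", "ignored", "skipped")))
  counts <- table(factor(verdicts,
                         c("positive", "negative", "ignored", "skipped")))
  expect_equal(sum(counts), nrow(grid))
})

test_that("classify_patch agrees with the per-pixel oracle (incl. verdict)", {
  set.seed(77)
  p <- scan_params()
  for (rep in 1:100) {
    side <- sample(c(20L, 40L), 1)
    x0 <- sample(0:30, 1); y0 <- sample(0:30, 1)
    patch <- boxes(x0, y0, x0 + side, y0 + side)
    gt <- random_boxes(sample(0:3, 1), 80L)
    px <- matrix(runif(side^2, 0.1, 0.9), side, side)  # always tissue
    cnt <- oracle_overlap_count(patch, gt)
    area <- side^2
    want <- if (2 * cnt > area) "positive" else
      if (10 * cnt < area) "negative" else "ignored"
    expect_equal(classify_patch(patch, px, gt, p), want)
  }
})

test_that("a gt box equal to one grid cell yields exactly one positive patch", {
  cases <- tibble::tibble(
    patient_id = "P1", laterality = "L", view = "CC",
    label = "positive", tier = "strong",
    image = list({
      m <- matrix(0.5, 128, 128); m[33:64, 65:96] <- 0.9; m
    }),
    boxes = list(boxes(64L, 32L, 96L, 64L))
  )
  ds <- build_patch_dataset(cases, patch_spec(32L), scan_params(),
                            balance = Inf)
  expect_equal(sum(ds$label == "positive"), 1)
  pos <- dplyr::filter(ds, label == "positive")
  expect_equal(pos$overlap_fraction, 1)
})

test_that("negative-only strong cases produce the oracle's tissue patch count", {
  img <- matrix(0, 128, 128)
  img[1:128, 1:80] <- 0.6  # left 80 columns are tissue
  cases <- tibble::tibble(
    patient_id = "P1", laterality = "L", view = "CC",
    label = "negative", tier = "strong",
    image = list(img), boxes = list(boxes())
  )
  ds <- build_patch_dataset(cases, patch_spec(32L), scan_params(),
                            balance = Inf)
  expect_true(all(ds$label == "negative"))
  grid <- tile(128L, patch_spec(32L))
  want <- sum(purrr::map_lgl(seq_len(nrow(grid)), function(j) {
    p <- grid[j, ]
    win <- img[(p$y0 + 1):p$y1, (p$x0 + 1):p$x1]
    mean(win > 0.02) > 0.3
  }))
  expect_equal(nrow(ds), want)
  expect_lte(nrow(ds), 16)
})

test_that("balance 1:1 subsamples negatives deterministically", {
  img <- matrix(0.5, 128, 128)
  img[1:64, 1:64] <- 0.9
  cases <- tibble::tibble(
    patient_id = "P1", laterality = "L", view = "CC",
    label = "positive", tier = "strong",
    image = list(img), boxes = list(boxes(0L, 0L, 64L, 64L))
  )
  ds <- build_patch_dataset(cases, patch_spec(32L), scan_params(),
                            balance = 1, seed = 4L)
  expect_equal(sum(ds$label == "positive"), sum(ds$label == "negative"))
  ds2 <- build_patch_dataset(cases, patch_spec(32L), scan_params(),
                             balance = 1, seed = 4L)
  expect_identical(ds, ds2)
})

test_that("weak-tier cases contribute no patches", {
  img <- matrix(0.5, 64, 64)
  cases <- tibble::tibble(
    patient_id = c("P1", "P2"), laterality = "L", view = "CC",
    label = c("negative", "negative"), tier = c("weak", "strong"),
    image = list(img, img), boxes = list(boxes(), boxes())
  )
  ds <- build_patch_dataset(cases, patch_spec(32L), scan_params(),
                            balance = Inf)
  expect_true(all(ds$case_id == "P2_L_CC"))
})

test_that("shrinking the patch size never loses positive patches", {
  img <- matrix(0.5, 128, 128)
  img[17:112, 17:112] <- 0.9
  gt <- boxes(16L, 16L, 112L, 112L)  # much larger than the smaller patches
  cases <- tibble::tibble(
    patient_id = "P1", laterality = "L", view = "CC",
    label = "positive", tier = "strong",
    image = list(img), boxes = list(gt)
  )
  n_pos <- purrr::map_int(c(64L, 32L, 16L), function(ps) {
    ds <- build_patch_dataset(cases, patch_spec(ps), scan_params(),
                              balance = Inf)
    sum(ds$label == "positive")
  })
  expect_true(all(diff(n_pos) >= 0))
})
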