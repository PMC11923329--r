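test_that("zero-initialized head yields logits (0,0) and probability 0.5", {
  m <- init_backbone(backbone_config("tiny"), seed = 1)
  out <- forward(m, matrix(runif(64^2), 64, 64))
  expect_equal(out$logits, c(0, 0))
  expect_equal(out$probability_positive, 0.5)
})

test_that("output shape is independent of input size (scale invariance)", {
  m <- init_backbone(backbone_config("tiny"), seed = 2)
  m$head$W <- matrix(rnorm(2 * 32, 0, 0.1), 2, 32)
  for (side in c(32, 64, 128)) {
    out <- forward(m, matrix(runif(side^2), side, side))
    expect_length(out$logits, 2)
    expect_true(out$probability_positive >= 0 && out$probability_positive <= 1)
  }
  ref <- init_backbone(backbone_config("reference"), seed = 3)
  for (side in c(128, 256, 512, 1024)) {
    out <- forward(ref, matrix(runif(side^2), side, side))
    expect_length(out$logits, 2)
  }
})

test_that("forward is deterministic and undersized input names the minimum", {
  m <- init_backbone(backbone_config("tiny"), seed = 4)
  m$head$W <- matrix(rnorm(64, 0, 0.1), 2, 32)
  img <- matrix(runif(32^2), 32, 32)
  expect_identical(forward(m, img), forward(m, img))
  expect_error(forward(m, matrix(0.5, 4, 4)), "minimum of 8")
})

test_that("softmax probabilities always sum to one", {
  m <- init_backbone(backbone_config("tiny"), seed = 5)
  m$head$W <- matrix(rnorm(64, 0, 1), 2, 32)
  for (i in 1:5) {
    f <- curripatch:::forward_cached(m, matrix(runif(32^2), 32, 32))
    expect_equal(sum(curripatch:::softmax2(f$logits)), 1)
  }
})

test_that("identity-kernel toy net exposes its input as final activations", {
  m <- toy_identity_model(scales = c(1, 0.5, 2))
  x <- matrix(runif(16^2, 0.1, 0.9), 16, 16)
  fca <- final_conv_activations(m, x)
  expect_equal(fca$activations[, , 1], x)
  expect_equal(fca$activations[, , 2], 0.5 * x)
  expect_equal(fca$activations[, , 3], 2 * x)
  # two calls agree exactly
  expect_identical(fca$activations, final_conv_activations(m, x)$activations)
})

test_that("logit gradients w.r.t. final activations equal the analytic form", {
  m <- toy_identity_model()
  x <- matrix(runif(12^2, 0.1, 0.9), 12, 12)
  fca <- final_conv_activations(m, x)
  hw <- 12^2
  for (k in 1:2) {
    g <- fca$grad(k)
    for (c in 1:3) {
      expect_equal(unique(as.vector(g[, , c])), m$head$W[k, c] / hw)
    }
  }
  # finite-difference check of the same derivative through the actual head:
  # logit_k as a function of one activation entry
  A <- fca$activations
  h <- 1e-5
  logit_of <- function(A) drop(m$head$W %*% apply(A, 3, mean) + m$head$b)
  for (probe in list(c(3, 4, 1), c(7, 2, 2), c(10, 11, 3))) {
    Ap <- A; Am <- A
    Ap[probe[1], probe[2], probe[3]] <- Ap[probe[1], probe[2], probe[3]] + h
    Am[probe[1], probe[2], probe[3]] <- Am[probe[1], probe[2], probe[3]] - h
    fd <- (logit_of(Ap)[2] - logit_of(Am)[2]) / (2 * h)
    expect_equal(fca$grad(2)[probe[1], probe[2], probe[3]], fd,
                 tolerance = 1e-6)
  }
})

test_that("backprop gradients match central finite differences", {
  set.seed(9)
  m <- init_backbone(backbone_config("tiny"), seed = 9)
  m$head$W <- matrix(rnorm(64, 0, 0.3), 2, 32)
  imgs <- list(matrix(runif(16^2), 16, 16), matrix(runif(16^2), 16, 16))
  classes <- c(1L, 2L)
  got <- curripatch:::batch_loss_grads(m, imgs, classes)
  loss_of <- function(model) curripatch:::batch_loss_grads(model, imgs, classes)$loss
  h <- 1e-5
  check <- function(getter, setter, analytic, n_probe = 6) {
    vals <- getter(m)
    idx <- sample(length(vals), min(n_probe, length(vals)))
    for (i in idx) {
      mp <- setter(m, i, vals[i] + h)
      mm <- setter(m, i, vals[i] - h)
      fd <- (loss_of(mp) - loss_of(mm)) / (2 * h)
      denom <- max(abs(fd), abs(analytic[i]))
      if (denom < 1e-6) {
        expect_lt(abs(fd - analytic[i]), 1e-9)  # both negligible
      } else {
        expect_lt(abs(fd - analytic[i]) / denom, 1e-4)
      }
    }
  }
  for (layer in 1:3) {
    check(
      function(m) m$conv[[layer]]$W,
      function(m, i, v) { m$conv[[layer]]$W[i] <- v; m },
      got$grads$conv[[layer]]$W
    )
    check(
      function(m) m$conv[[layer]]$b,
      function(m, i, v) { m$conv[[layer]]$b[i] <- v; m },
      got$grads$conv[[layer]]$b, n_probe = 3
    )
  }
  check(
    function(m) m$head$W,
    function(m, i, v) { m$head$W[i] <- v; m },
    got$grads$head$W
  )
})
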