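#' Configure the scale-invariant convolutional backbone
#'
#' A stack of 3x3 convolution blocks (ReLU, 2x2 average pooling after the
#' early blocks) closed by global adaptive average pooling and a linear
#' two-class head. Global pooling makes the output dimensionality independent
#' of the input size, so one set of weights serves every curriculum stage,
#' from the smallest patches to full images.
#'
#' Two variants are provided. `"tiny"` (three blocks, ~6k parameters) is the
#' trainable desk-scale model; `"reference"` is a wider, deeper stand-in for
#' a large production classifier and is exercised shape-wise. The minimum
#' input side is `2^n_pools * 2` (8 px for tiny, 16 px for reference);
#' inputs must be square with a side divisible by `2^n_pools`.
#'
#' @param architecture `"tiny"` or `"reference"`.
#' @param n_classes Number of output classes (2: cancer vs no cancer).
#' @param channels Integer vector of per-block output channels (defaults by
#'   architecture).
#' @return A `backbone_config` list.
#' @export
backbone_config <- function(architecture = c("tiny", "reference"),
                            n_classes = 2L, channels = NULL) {
  architecture <- match.arg(architecture)
  channels <- channels %||% switch(architecture,
    tiny = c(8L, 16L, 32L),
    reference = c(32L, 64L, 128L, 256L)
  )
  n_blocks <- length(channels)
  pools <- c(rep(TRUE, n_blocks - 1L), FALSE)
  structure(list(
    architecture = architecture,
    n_classes = as.integer(n_classes),
    channels = as.integer(channels),
    pools = pools,
    min_input = as.integer(2^sum(pools) * 2)
  ), class = "backbone_config")
}

#' Initialize backbone weights
#'
#' He-scaled Gaussian initialization of the convolution stacks and a
#' zero-initialized linear head (so an untrained model outputs probability
#' 0.5 for every input).
#'
#' @param config A [backbone_config()].
#' @param seed RNG seed; the same seed reproduces the same weights.
#' @return A `curri_backbone` model object.
#' @export
init_backbone <- function(config = backbone_config(), seed = 1L) {
  set.seed(as.integer(seed))
  cin <- 1L
  conv <- vector("list", length(config$channels))
  for (i in seq_along(config$channels)) {
    cout <- config$channels[i]
    sd <- sqrt(2 / (9 * cin))
    conv[[i]] <- list(
      W = matrix(rnorm(cout * 9 * cin, 0, sd), cout, 9 * cin),
      b = numeric(cout)
    )
    cin <- cout
  }
  head <- list(W = matrix(0, config$n_classes, cin),
               b = numeric(config$n_classes))
  structure(list(config = config, conv = conv, head = head),
            class = "curri_backbone")
}

check_input_size <- function(model, image) {
  cfg <- model$config
  if (nrow(image) != ncol(image)) abort("input must be square")
  if (nrow(image) < cfg$min_input) {
    abort(paste0("input side ", nrow(image), " is below the network minimum of ",
                 cfg$min_input, " pixels"))
  }
  if (nrow(image) %% (2^sum(cfg$pools)) != 0) {
    abort(paste0("input side must be divisible by ", 2^sum(cfg$pools)))
  }
}

# Forward pass with cached intermediates for backprop.
forward_cached <- function(model, image) {
  check_input_size(model, image)
  x <- array(image, dim = c(nrow(image), ncol(image), 1L))
  cache <- list(inputs = list(), prerelu = list(), postrelu = list())
  for (i in seq_along(model$conv)) {
    cache$inputs[[i]] <- x
    z <- conv3_forward(x, model$conv[[i]]$W, model$conv[[i]]$b)
    cache$prerelu[[i]] <- z
    a <- z * (z > 0)
    cache$postrelu[[i]] <- a
    x <- if (model$config$pools[i]) avgpool2_forward(a) else a
  }
  feat <- apply(x, 3, mean)
  logits <- drop(model$head$W %*% feat + model$head$b)
  cache$final <- x
  cache$feat <- feat
  list(logits = logits, cache = cache)
}

softmax2 <- function(logits) {
  e <- exp(logits - max(logits))
  e / sum(e)
}

#' Forward pass: two-class scores for a square image
#'
#' @param model A `curri_backbone`.
#' @param image Square numeric matrix (any side the architecture accepts).
#' @return List with `logits` (length-2) and `probability_positive` (softmax
#'   probability of the cancer class, class 2).
#' @export
forward <- function(model, image) {
  f <- forward_cached(model, image)
  p <- softmax2(f$logits)
  list(logits = f$logits, probability_positive = p[2])
}

# Backprop of dlogits through the network; returns gradient lists matching
# the weight structure, plus nothing else (dx is not needed at the root).
backward_from_logits <- function(model, cache, dlogits) {
  grads <- list(conv = vector("list", length(model$conv)), head = NULL)
  feat <- cache$feat
  grads$head <- list(W = outer(dlogits, feat), b = dlogits)
  dfeat <- drop(t(model$head$W) %*% dlogits)
  fin <- cache$final
  hw <- dim(fin)[1] * dim(fin)[2]
  dx <- array(rep(dfeat / hw, each = hw), dim = dim(fin))
  for (i in rev(seq_along(model$conv))) {
    if (model$config$pools[i]) dx <- avgpool2_backward(dx)
    dz <- dx * (cache$prerelu[[i]] > 0)
    bk <- conv3_backward(cache$inputs[[i]], model$conv[[i]]$W, dz)
    grads$conv[[i]] <- list(W = bk$dW, b = as.numeric(bk$db))
    dx <- bk$dx
  }
  grads
}

#' Final-convolution activations and their logit gradients
#'
#' Returns the activation maps of the last convolutional stage (post-ReLU)
#' together with a function giving the gradient of a chosen class logit with
#' respect to those maps — the two ingredients of Grad-CAM.
#'
#' @param model A `curri_backbone`.
#' @param image Square numeric matrix.
#' @return List with `activations` (H' x W' x C array) and
#'   `grad(target_class)` returning an array of the same shape.
#' @export
final_conv_activations <- function(model, image) {
  f <- forward_cached(model, image)
  acts <- f$cache$final
  hw <- dim(acts)[1] * dim(acts)[2]
  headW <- model$head$W
  list(
    activations = acts,
    logits = f$logits,
    grad = function(target_class) {
      # logit_k = sum_c W[k, c] * mean(A_c) + b[k]; the gradient is constant
      # W[k, c] / (H'W') over each channel's spatial positions.
      array(rep(headW[target_class, ] / hw, each = hw), dim = dim(acts))
    }
  )
}

# Mean cross-entropy loss and accumulated gradients over a minibatch of
# (image, class) pairs. class is 1 (negative) or 2 (positive).
batch_loss_grads <- function(model, images, classes) {
  n <- length(images)
  total_loss <- 0
  acc <- NULL
  for (i in seq_len(n)) {
    f <- forward_cached(model, images[[i]])
    p <- softmax2(f$logits)
    total_loss <- total_loss - log(max(p[classes[i]], 1e-12))
    dlogits <- p
    dlogits[classes[i]] <- dlogits[classes[i]] - 1
    g <- backward_from_logits(model, f$cache, dlogits / n)
    acc <- if (is.null(acc)) g else add_grads(acc, g)
  }
  list(loss = total_loss / n, grads = acc)
}

add_grads <- function(a, b) {
  for (i in seq_along(a$conv)) {
    a$conv[[i]]$W <- a$conv[[i]]$W + b$conv[[i]]$W
    a$conv[[i]]$b <- a$conv[[i]]$b + b$conv[[i]]$b
  }
  a$head$W <- a$head$W + b$head$W
  a$head$b <- a$head$b + b$head$b
  a
}

# Adam state and update, operating on the model's weight structure.
adam_init <- function(model) {
  zero_like <- function(x) if (is.matrix(x)) 0 * x else numeric(length(x))
  list(
    t = 0,
    m = list(conv = lapply(model$conv, lapply, zero_like),
             head = lapply(model$head, zero_like)),
    v = list(conv = lapply(model$conv, lapply, zero_like),
             head = lapply(model$head, zero_like))
  )
}

adam_step <- function(model, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  upd <- function(w, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^state$t)
    vh <- v / (1 - beta2^state$t)
    list(w = w - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  for (i in seq_along(model$conv)) {
    for (nm in c("W", "b")) {
      u <- upd(model$conv[[i]][[nm]], grads$conv[[i]][[nm]],
               state$m$conv[[i]][[nm]], state$v$conv[[i]][[nm]])
      model$conv[[i]][[nm]] <- u$w
      state$m$conv[[i]][[nm]] <- u$m
      state$v$conv[[i]][[nm]] <- u$v
    }
  }
  for (nm in c("W", "b")) {
    u <- upd(model$head[[nm]], grads$head[[nm]],
             state$m$head[[nm]], state$v$head[[nm]])
    model$head[[nm]] <- u$w
    state$m$head[[nm]] <- u$m
    state$v$head[[nm]] <- u$v
  }
  list(model = model, state = state)
}
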