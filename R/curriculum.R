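#' Curriculum training configuration
#'
#' The training schedule: three patch stages of increasing size
#' (128, 256, 512 by default), then a final stage on full-size images with
#' image-level labels. `strong_fraction` selects the supervision regime:
#' 0 is the weakly supervised baseline (patch stages skipped entirely),
#' 0.2/0.4/1.0 are the curriculum-20/40/100 regimes. The full-fidelity
#' defaults follow the reference schedule (100 epochs per patch stage,
#' 15 full-image epochs, Adam at learning rate 1e-05, flip/rotation
#' augmentation, ten repeated runs); see [desk_preset()] for a schedule
#' sized for a laptop CPU.
#'
#' @param stage_patch_sizes Strictly increasing patch sides in pixels.
#' @param stage_epochs Epochs per patch stage (scalar or one per stage).
#' @param final_epochs Epochs of full-image training.
#' @param baseline_epochs Full-image epochs when `strong_fraction = 0`.
#'   Defaults to `final_epochs` (the baseline trains only the final stage);
#'   set it higher to grant the baseline a matched update budget.
#' @param learning_rate Adam step size.
#' @param strong_fraction Fraction of patients with bounding-box supervision.
#' @param n_runs Number of repeated training runs (metrics are mean +- SD).
#' @param augmentation Apply random flips and 90-degree rotations during
#'   training.
#' @param batch_size Minibatch size.
#' @param balance Negative:positive patch ratio per stage.
#' @param max_stage_samples Cap on patch samples per stage (seeded,
#'   label-stratified subsample); `Inf` keeps everything.
#' @param reset_optimizer Reset Adam state at stage boundaries (weights
#'   always persist across stages).
#' @param seeds Optional integer vector of per-run seeds (length `n_runs`).
#' @return A `curriculum_config` list.
#' @export
curriculum_config <- function(stage_patch_sizes = c(128L, 256L, 512L),
                              stage_epochs = 100L, final_epochs = 15L,
                              baseline_epochs = NULL,
                              learning_rate = 1e-05, strong_fraction = 1.0,
                              n_runs = 10L, augmentation = TRUE,
                              batch_size = 8L, balance = 1,
                              max_stage_samples = Inf,
                              reset_optimizer = TRUE, seeds = NULL) {
  stage_patch_sizes <- as.integer(stage_patch_sizes)
  if (length(stage_patch_sizes) > 1 && any(diff(stage_patch_sizes) <= 0)) {
    abort("stage_patch_sizes must be strictly increasing")
  }
  if (strong_fraction < 0 || strong_fraction > 1) {
    abort("strong_fraction must lie in [0, 1]")
  }
  if (!is.null(seeds) && length(seeds) != n_runs) {
    abort("length(seeds) must equal n_runs")
  }
  structure(list(
    stage_patch_sizes = stage_patch_sizes,
    stage_epochs = as.integer(rep(stage_epochs,
                                  length.out = length(stage_patch_sizes))),
    final_epochs = as.integer(final_epochs),
    baseline_epochs = as.integer(baseline_epochs %||% final_epochs),
    learning_rate = learning_rate,
    strong_fraction = strong_fraction,
    n_runs = as.integer(n_runs),
    augmentation = isTRUE(augmentation),
    batch_size = as.integer(batch_size),
    balance = balance,
    max_stage_samples = max_stage_samples,
    reset_optimizer = isTRUE(reset_optimizer),
    seeds = if (is.null(seeds)) NULL else as.integer(seeds)
  ), class = "curriculum_config")
}

rot_cw <- function(m) t(m[nrow(m):1, , drop = FALSE])

augment_image <- function(m) {
  k <- sample(0:3, 1)
  if (k > 0) for (i in seq_len(k)) m <- rot_cw(m)
  if (runif(1) < 0.5) m <- m[, ncol(m):1, drop = FALSE]
  if (runif(1) < 0.5) m <- m[nrow(m):1, , drop = FALSE]
  m
}

#' Train the model on one curriculum stage
#'
#' Minimizes two-class cross-entropy with Adam at a fixed learning rate over
#' a set of labeled samples (patch samples or full images). Augmentation
#' (random horizontal/vertical flips and rotations in multiples of 90
#' degrees) is applied to training samples only. `epochs = 0` returns the
#' model unchanged.
#'
#' @param model A `curri_backbone`.
#' @param samples Tibble with `pixels` (list of square matrices) and `label`
#'   (`"positive"`/`"negative"`); both classes must be present.
#' @param epochs Number of passes over the samples.
#' @param learning_rate Adam step size.
#' @param augmentation Logical.
#' @param batch_size Minibatch size.
#' @param seed RNG seed for shuffling and augmentation.
#' @param stage_name Used in error messages.
#' @return List with the updated `model` and the per-epoch `loss` trajectory.
#' @export
train_stage <- function(model, samples, epochs, learning_rate = 1e-05,
                        augmentation = TRUE, batch_size = 8L, seed = 1L,
                        stage_name = "stage") {
  if (nrow(samples) == 0) abort(paste0(stage_name, ": empty sample list"))
  if (length(unique(samples$label)) < 2) {
    abort(paste0(stage_name, ": training data contains a single class"))
  }
  if (epochs == 0) return(list(model = model, loss = numeric(0)))
  classes <- ifelse(samples$label == "positive", 2L, 1L)
  set.seed(as.integer(seed))
  state <- adam_init(model)
  losses <- numeric(epochs)
  n <- nrow(samples)
  for (ep in seq_len(epochs)) {
    ord <- sample(n)
    ep_loss <- 0
    done <- 0
    while (done < n) {
      idx <- ord[(done + 1):min(done + batch_size, n)]
      imgs <- lapply(samples$pixels[idx], function(m) {
        if (augmentation) augment_image(m) else m
      })
      bg <- batch_loss_grads(model, imgs, classes[idx])
      if (!is.finite(bg$loss)) {
        abort(paste0(stage_name, ": training diverged (non-finite loss)"))
      }
      st <- adam_step(model, bg$grads, state, learning_rate)
      model <- st$model
      state <- st$state
      ep_loss <- ep_loss + bg$loss * length(idx)
      done <- done + length(idx)
    }
    losses[ep] <- ep_loss / n
  }
  list(model = model, loss = losses)
}

full_image_samples <- function(cases) {
  tibble(pixels = cases$image, label = cases$label)
}

#' Run the staged curriculum for one seed
#'
#' Executes the patch stages in order of increasing patch size on strong-tier
#' cases, then the final full-image stage on all cases with image-level
#' labels. With `strong_fraction = 0` only the final stage runs — this *is*
#' the baseline model, not a separate code path. Weights persist across
#' stages; the optimizer state is reset at stage boundaries by default.
#'
#' @param cases Preprocessed cohort tibble with tiers assigned.
#' @param config A [curriculum_config()].
#' @param seed Seed for weight init, sampling, shuffling and augmentation.
#' @param backbone A [backbone_config()].
#' @param params A [scan_params()] for patch skip rules.
#' @return A `curri_run`: trained model, per-stage log, loss trajectories.
#' @export
run_curriculum <- function(cases, config = curriculum_config(), seed = 1L,
                           backbone = backbone_config("tiny"),
                           params = scan_params()) {
  model <- init_backbone(backbone, seed)
  stage_log <- list()
  losses <- list()
  if (config$strong_fraction > 0) {
    strong <- filter(cases, .data$tier == "strong")
    if (!any(strong$label == "positive")) {
      abort("strong_fraction > 0 but the cohort has no strong positive cases")
    }
    for (si in seq_along(config$stage_patch_sizes)) {
      ps <- config$stage_patch_sizes[si]
      stage_seed <- patient_seed(seed, si)
      ds <- build_patch_dataset(cases, patch_spec(ps), params,
                                balance = config$balance, seed = stage_seed)
      if (is.finite(config$max_stage_samples) &&
          nrow(ds) > config$max_stage_samples) {
        set.seed(stage_seed)
        ds <- ds |>
          group_by(.data$label) |>
          dplyr::slice_sample(prop = config$max_stage_samples / nrow(ds)) |>
          ungroup() |>
          arrange(.data$case_id, .data$y0, .data$x0)
      }
      tr <- train_stage(model, ds, config$stage_epochs[si],
                        config$learning_rate, config$augmentation,
                        config$batch_size, seed = stage_seed,
                        stage_name = paste0("patch-", ps))
      model <- tr$model
      stage_log[[length(stage_log) + 1]] <- tibble(
        stage = paste0("patch-", ps), patch_size = ps,
        epochs = config$stage_epochs[si], n_samples = nrow(ds),
        final_loss = if (length(tr$loss)) tr$loss[length(tr$loss)] else NA_real_
      )
      losses[[paste0("patch-", ps)]] <- tr$loss
    }
  }
  final_epochs <- if (config$strong_fraction > 0) config$final_epochs else
    config$baseline_epochs
  full <- full_image_samples(cases)
  tr <- train_stage(model, full, final_epochs, config$learning_rate,
                    config$augmentation, config$batch_size,
                    seed = patient_seed(seed, 97L), stage_name = "full-image")
  model <- tr$model
  stage_log[[length(stage_log) + 1]] <- tibble(
    stage = "full-image", patch_size = nrow(cases$image[[1]]),
    epochs = final_epochs, n_samples = nrow(full),
    final_loss = if (length(tr$loss)) tr$loss[length(tr$loss)] else NA_real_
  )
  losses[["full-image"]] <- tr$loss
  structure(list(
    model = model,
    stages = bind_rows(stage_log),
    losses = losses,
    seed = as.integer(seed),
    config = config
  ), class = "curri_run")
}

#' Repeat the curriculum over several seeds
#'
#' One independent training run per seed; downstream metrics are reported as
#' mean +- SD over the runs.
#'
#' @inheritParams run_curriculum
#' @return List of `curri_run` objects, one per seed.
#' @export
repeat_runs <- function(cases, config = curriculum_config(),
                        backbone = backbone_config("tiny"),
                        params = scan_params()) {
  if (config$n_runs < 1) abort("n_runs must be >= 1")
  seeds <- config$seeds %||% seq_len(config$n_runs)
  purrr::map(seeds, ~ run_curriculum(cases, config, .x, backbone, params))
}

#' @export
print.curri_run <- function(x, ...) {
  cat("<curri_run> seed", x$seed, "\n")
  print(x$stages)
  invisible(x)
}
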