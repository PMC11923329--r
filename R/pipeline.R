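#' Patient-level development/test split
#'
#' Splits a cohort by patient (all views of a patient stay on one side),
#' stratified by the patient's label, with the development side sized to
#' `round(dev_fraction * n_patients)` exactly (largest-remainder
#' apportionment across strata). A stratum with fewer than two patients
#' triggers a warning and an unstratified split.
#'
#' @param cases Cohort tibble (or any tibble with `patient_id` and `label`
#'   columns; a patient is positive when any of their rows is).
#' @param dev_fraction Development fraction in (0, 1); 0.75 by default.
#' @param seed RNG seed for the draw.
#' @return List with `development` and `test` tibbles.
#' @export
split_cohort <- function(cases, dev_fraction = 0.75, seed = 1L) {
  if (dev_fraction <= 0 || dev_fraction >= 1) {
    abort("dev_fraction must lie in (0, 1)")
  }
  pat <- cases |>
    group_by(.data$patient_id) |>
    summarise(label = if (any(.data$label == "positive")) "positive" else "negative",
              .groups = "drop")
  n_dev <- round(dev_fraction * nrow(pat))
  strata <- split(pat$patient_id, pat$label)
  if (any(lengths(strata) < 2)) {
    warn("a label stratum has fewer than 2 patients; splitting unstratified")
    strata <- list(all = pat$patient_id)
  }
  quota <- vapply(strata, function(p) dev_fraction * length(p), numeric(1))
  base <- floor(quota)
  rem <- n_dev - sum(base)
  ord <- order(quota - base, decreasing = rem > 0)
  if (rem != 0) {
    pick <- ord[seq_len(abs(rem))]
    base[pick] <- base[pick] + sign(rem)
  }
  set.seed(as.integer(seed))
  dev_ids <- unlist(purrr::map2(strata, base, function(ids, k) {
    sample(ids, min(max(k, 0), length(ids)))
  }), use.names = FALSE)
  list(
    development = filter(cases, .data$patient_id %in% dev_ids),
    test = filter(cases, !.data$patient_id %in% dev_ids)
  )
}

#' Full pipeline configuration
#'
#' One structured configuration drives the whole simulate -> preprocess ->
#' train -> evaluate -> explain pipeline; it round-trips through YAML (see
#' [write_pipeline_config()]).
#'
#' @param phantom A [phantom_config()].
#' @param scan A [scan_params()].
#' @param target_size Network input side after preprocessing.
#' @param backbone A [backbone_config()].
#' @param curriculum A [curriculum_config()]; its `strong_fraction` is
#'   overridden per regime.
#' @param regimes Strong-annotation fractions to run (default baseline,
#'   curriculum-20, curriculum-40, curriculum-100).
#' @param dev_fraction Development split fraction.
#' @param threshold Breast-level decision threshold.
#' @param xai_budget `"gt"` or `"top5pct"` top-pixel rule.
#' @param seed Global seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(phantom = phantom_config(),
                            scan = scan_params(),
                            target_size = 1024L,
                            backbone = backbone_config("tiny"),
                            curriculum = curriculum_config(),
                            regimes = c(0, 0.2, 0.4, 1.0),
                            dev_fraction = 0.75, threshold = 0.5,
                            xai_budget = "gt", seed = 1L) {
  structure(list(
    phantom = phantom, scan = scan, target_size = as.integer(target_size),
    backbone = backbone, curriculum = curriculum, regimes = regimes,
    dev_fraction = dev_fraction, threshold = threshold,
    xai_budget = xai_budget, seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' Desk-scale preset
#'
#' A configuration sized for a single CPU: 60-patient phantom cohort at a
#' small native resolution, 128-pixel network input, two patch stages
#' (16, 32) plus the full-image stage, short epochs at a larger learning
#' rate, and the tiny backbone. It preserves the structure of the
#' full-fidelity schedule (patch stages of increasing size, then full
#' images) at roughly 1/64 of the pixel budget. Lesions are proportionally
#' larger than clinical lesions so that every patch stage keeps both classes
#' populated at this resolution.
#'
#' @param n_runs Repeated training runs per regime.
#' @param regimes Strong-annotation fractions to run.
#' @param seed Global seed.
#' @return A `pipeline_config`.
#' @export
desk_preset <- function(n_runs = 5L, regimes = c(0, 0.2, 1.0), seed = 1L) {
  pipeline_config(
    phantom = phantom_config(
      image_height = 192L, image_width = 160L, n_patients = 60L,
      cancer_fraction = 0.5, lesion_count_range = c(1L, 2L),
      lesion_radius_range = c(28L, 36L), lesion_contrast = 0.35,
      background_noise_sd = 0.008, seed = seed
    ),
    scan = scan_params(scan_patch_size = 48L, scan_stride = 16L),
    target_size = 128L,
    backbone = backbone_config("tiny"),
    curriculum = curriculum_config(
      stage_patch_sizes = c(16L, 32L), stage_epochs = 6L, final_epochs = 3L,
      learning_rate = 1e-3, n_runs = n_runs, batch_size = 8L,
      max_stage_samples = 400
    ),
    regimes = regimes, dev_fraction = 0.75, threshold = 0.5,
    xai_budget = "gt", seed = seed
  )
}

#' Run the full pipeline
#'
#' Simulates the phantom cohort, splits it by patient, preprocesses both
#' sides, then for every requested supervision regime assigns annotation
#' tiers, trains `n_runs` repeated curricula on the development side, and
#' scores breast-level recall/precision/F1 and the ground-truth overlap
#' ratio on the held-out test side. The summary table has one row per
#' regime with each metric as mean +- SD over runs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory for artifacts (config snapshot,
#'   per-run metrics CSV, summary CSV/JSON, JSON-lines log). Every artifact
#'   records the config hash and seed that produced it.
#' @return A `curri_result`: list with `per_run` and `summary` tibbles,
#'   `config`, and `config_hash`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  hash <- rlang::hash(unclass_deep(config))
  log_lines <- character(0)
  log_event <- function(...) {
    line <- jsonlite::toJSON(list(...), auto_unbox = TRUE)
    log_lines <<- c(log_lines, as.character(line))
  }
  log_event(event = "start", config_hash = hash, seed = config$seed)
  cohort <- generate_cohort(config$phantom)
  parts <- split_cohort(cohort, config$dev_fraction, config$seed)
  dev <- preprocess_cohort(parts$development, config$scan, config$target_size)
  test <- preprocess_cohort(parts$test, config$scan, config$target_size)
  log_event(event = "preprocessed", dev_views = nrow(dev),
            test_views = nrow(test))
  per_run <- list()
  for (sf in config$regimes) {
    regime <- regime_name(sf)
    cc <- config$curriculum
    cc$strong_fraction <- sf
    dev_t <- assign_annotation_tiers(dev, sf, seed = config$seed)
    runs <- repeat_runs(dev_t, cc, config$backbone, config$scan)
    for (run in runs) {
      ev <- evaluate_run(run$model, test, config$threshold)
      ov <- cohort_overlap(run$model, test, config$xai_budget)
      per_run[[length(per_run) + 1]] <- bind_cols(
        tibble(regime = regime, strong_fraction = sf, seed = run$seed),
        select(ev, "recall", "precision", "f1"),
        tibble(overlap_ratio = ov$summary$mean)
      )
      log_event(event = "run", regime = regime, seed = run$seed,
                f1 = ev$f1, overlap = ov$summary$mean)
    }
  }
  per_run <- bind_rows(per_run)
  summary <- per_run |>
    group_by(.data$regime, .data$strong_fraction) |>
    summarise(across(c("overlap_ratio", "recall", "precision", "f1"),
                     list(mean = mean, sd = ~ if (n() == 1) 0 else sd(.x))),
              n_runs = n(), .groups = "drop") |>
    arrange(.data$strong_fraction)
  result <- structure(list(per_run = per_run, summary = summary,
                           config = config, config_hash = hash),
                      class = "curri_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_pipeline_config(config, file.path(out_dir, "config.yaml"))
    meta <- per_run |> mutate(config_hash = hash)
    utils::write.csv(meta, file.path(out_dir, "metrics_per_run.csv"),
                     row.names = FALSE)
    utils::write.csv(summary |> mutate(config_hash = hash),
                     file.path(out_dir, "metrics_summary.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(config_hash = hash, seed = config$seed, summary = summary),
      file.path(out_dir, "metrics_summary.json"),
      dataframe = "rows", auto_unbox = TRUE, digits = NA
    )
    writeLines(log_lines, file.path(out_dir, "log.jsonl"))
  }
  result
}

regime_name <- function(sf) {
  if (sf == 0) "baseline" else paste0("curriculum-", round(100 * sf))
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

#' @export
print.curri_result <- function(x, ...) {
  cat("<curri_result> config", substr(x$config_hash, 1, 8), "\n")
  print(x$summary)
  invisible(x)
}

#' Write / read a pipeline configuration as YAML
#'
#' The configuration round-trips unchanged: `read_pipeline_config()`
#' rebuilds the classed sub-configurations through their constructors.
#'
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @return `write_pipeline_config()` returns `path` invisibly;
#'   `read_pipeline_config()` returns the `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass_deep(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  pipeline_config(
    phantom = do.call(phantom_config, raw$phantom),
    scan = do.call(scan_params, raw$scan),
    target_size = raw$target_size,
    backbone = backbone_config(raw$backbone$architecture,
                               raw$backbone$n_classes,
                               raw$backbone$channels),
    curriculum = do.call(curriculum_config, raw$curriculum),
    regimes = raw$regimes,
    dev_fraction = raw$dev_fraction,
    threshold = raw$threshold,
    xai_budget = raw$xai_budget,
    seed = raw$seed
  )
}
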