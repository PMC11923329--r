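#' Average ipsilateral view probabilities
#'
#' A breast's score is the arithmetic mean of the predicted probabilities of
#' its available views (CC and MLO of the same side).
#'
#' @param view_probs Numeric vector of per-view probabilities (length >= 1).
#' @return Single probability.
#' @export
aggregate_breast <- function(view_probs) {
  if (length(view_probs) == 0) abort("missing views: no probabilities to aggregate")
  mean(view_probs)
}

#' Predict view-level cancer probabilities
#'
#' Runs the classifier over every view of a (preprocessed) cohort.
#'
#' @param model A `curri_backbone`.
#' @param cases Preprocessed cohort tibble.
#' @return The cohort with a `probability` column (image columns dropped).
#' @export
predict_views <- function(model, cases) {
  probs <- purrr::map_dbl(cases$image,
                          ~ forward(model, .x)$probability_positive)
  cases |>
    mutate(probability = probs) |>
    select(-dplyr::any_of(c("image", "transform")))
}

#' Breast-level predictions from view probabilities
#'
#' Aggregates view probabilities per breast (patient x laterality), applies
#' the decision threshold, and attaches the true breast label (positive iff
#' any view of that breast is positive).
#'
#' @param view_preds Output of [predict_views()].
#' @param threshold Decision threshold on the aggregated probability
#'   (predicted positive when `aggregate >= threshold`).
#' @return Tibble with one row per breast: `patient_id`, `laterality`,
#'   `probability`, `predicted`, `truth`.
#' @export
breast_predictions <- function(view_preds, threshold = 0.5) {
  view_preds |>
    group_by(.data$patient_id, .data$laterality) |>
    summarise(
      probability = aggregate_breast(.data$probability),
      truth = if (any(.data$label == "positive")) "positive" else "negative",
      .groups = "drop"
    ) |>
    mutate(predicted = ifelse(.data$probability >= threshold,
                              "positive", "negative"))
}

#' Confusion counts over breast-level predictions
#'
#' @param predictions Tibble from [breast_predictions()].
#' @return Named list `TP`, `FP`, `TN`, `FN` (positive = cancer).
#' @export
confusion_counts <- function(predictions) {
  p <- predictions$predicted == "positive"
  t <- predictions$truth == "positive"
  list(TP = sum(p & t), FP = sum(p & !t), TN = sum(!p & !t), FN = sum(!p & t))
}

#' Precision, recall and F1 on the 0-100 scale
#'
#' Zero denominators yield 0 with a `degenerate` flag rather than an error.
#'
#' @param TP,FP,FN Non-negative counts.
#' @return Tibble with `precision`, `recall`, `f1`, `degenerate`.
#' @export
prf1 <- function(TP, FP, FN) {
  degenerate <- FALSE
  precision <- if (TP + FP == 0) { degenerate <- TRUE; 0 } else 100 * TP / (TP + FP)
  recall <- if (TP + FN == 0) { degenerate <- TRUE; 0 } else 100 * TP / (TP + FN)
  f1 <- if (precision + recall == 0) { degenerate <- TRUE; 0 } else
    2 * precision * recall / (precision + recall)
  if (degenerate) {
    warn("degenerate confusion counts: a zero denominator was scored as 0")
  }
  tibble(precision = precision, recall = recall, f1 = f1,
         degenerate = degenerate)
}

#' Breast-level metrics for one trained run
#'
#' @param model A `curri_backbone`.
#' @param cases Preprocessed test cohort.
#' @param threshold Decision threshold.
#' @return One-row tibble: precision, recall, F1 (0-100), counts.
#' @export
evaluate_run <- function(model, cases, threshold = 0.5) {
  preds <- breast_predictions(predict_views(model, cases), threshold)
  cc <- confusion_counts(preds)
  bind_cols(prf1(cc$TP, cc$FP, cc$FN), as_tibble(cc))
}

#' Mean and standard deviation over repeated runs
#'
#' Sample SD (n-1 denominator); a single run reports SD 0 and is flagged.
#'
#' @param per_run Numeric vector, one value per run.
#' @return Tibble with `mean`, `sd`, `n`, `single_run` flag.
#' @export
summarize_runs <- function(per_run) {
  if (length(per_run) < 1) abort("at least one run is required")
  single <- length(per_run) == 1
  tibble(mean = mean(per_run), sd = if (single) 0 else sd(per_run),
         n = length(per_run), single_run = single)
}
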