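#' Tidy a pipeline result
#'
#' One row per regime and metric with the mean and SD over repeated runs —
#' the long form of the summary table.
#'
#' @param x A `curri_result` from [run_pipeline()].
#' @param ... Unused.
#' @return Tibble with `regime`, `strong_fraction`, `metric`, `mean`, `sd`,
#'   `n_runs`.
#' @export
tidy.curri_result <- function(x, ...) {
  x$summary |>
    tidyr::pivot_longer(
      cols = tidyr::matches("_(mean|sd)$"),
      names_to = c("metric", ".value"),
      names_pattern = "(.*)_(mean|sd)$"
    )
}

#' @export
glance.curri_result <- function(x, ...) {
  best <- x$summary |> arrange(dplyr::desc(.data$f1_mean)) |> utils::head(1)
  tibble(
    n_regimes = nrow(x$summary),
    n_runs = best$n_runs,
    best_regime = best$regime,
    best_f1 = best$f1_mean,
    config_hash = x$config_hash
  )
}

#' @export
tidy.curri_run <- function(x, ...) x$stages

#' @export
glance.curri_run <- function(x, ...) {
  tibble(
    seed = x$seed,
    n_stages = nrow(x$stages),
    final_loss = x$stages$final_loss[nrow(x$stages)],
    total_epochs = sum(x$stages$epochs)
  )
}

#' Plot regime metrics
#'
#' Mean +- SD of each breast-level metric (and the overlap ratio) by
#' supervision regime.
#'
#' @param object A `curri_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.curri_result <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$regime, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      width = 0.2
    ) +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = NULL, y = "score (0-100)",
                  title = "Breast-level performance by supervision regime") +
    ggplot2::theme_minimal()
}

#' Overlay a saliency map and ground-truth boxes on an image
#'
#' @param image Numeric matrix in `[0, 1]`.
#' @param saliency Matrix from [grad_cam()] (same size), or `NULL`.
#' @param gt_boxes Box tibble, or `NULL`.
#' @return A ggplot.
#' @export
plot_saliency <- function(image, saliency = NULL, gt_boxes = NULL) {
  d <- tidyr::expand_grid(y = seq_len(nrow(image)) - 1L,
                          x = seq_len(ncol(image)) - 1L)
  d$intensity <- as.vector(t(image))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
  if (!is.null(saliency)) {
    d$sal <- as.vector(t(saliency))
    p <- p + ggplot2::geom_raster(
      data = d[d$sal > 0.5, ],
      ggplot2::aes(x = .data$x, y = .data$y),
      fill = "red", alpha = 0.35
    )
  }
  if (!is.null(gt_boxes) && nrow(gt_boxes) > 0) {
    p <- p + ggplot2::geom_rect(
      data = gt_boxes,
      ggplot2::aes(xmin = .data$x0, xmax = .data$x1,
                   ymin = .data$y0, ymax = .data$y1),
      inherit.aes = FALSE, fill = NA, colour = "cyan", linewidth = 0.6
    )
  }
  p
}
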