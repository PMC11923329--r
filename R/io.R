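#' Read a grayscale image from PNG or TIFF
#'
#' 8- and 16-bit inputs are rescaled to `[0, 1]`; multi-channel images are
#' averaged to one channel. Rows index y, columns x.
#'
#' @param path File path ending in `.png`, `.tif` or `.tiff`.
#' @return Numeric matrix in `[0, 1]`.
#' @export
read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    abort(paste0("unsupported image format: .", ext))
  )
  if (length(dim(img)) == 3) img <- apply(img, c(1, 2), mean)
  pmin(pmax(img, 0), 1)
}

#' Write a cohort to disk: 16-bit TIFF images plus a CSV manifest
#'
#' The manifest has one row per (case, box) pair — cases without boxes get a
#' single row with empty box fields — and columns `patient_id`, `laterality`,
#' `view`, `label`, `tier`, `image_path`, `x0`, `y0`, `x1`, `y1` (0-based,
#' half-open). Images round-trip at 16-bit precision.
#'
#' @param cases Cohort tibble.
#' @param dir Output directory (created if needed).
#' @return The manifest tibble, invisibly.
#' @export
write_cohort <- function(cases, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  rows <- vector("list", nrow(cases))
  for (i in seq_len(nrow(cases))) {
    rel <- file.path("images", paste0(
      cases$patient_id[i], "_", cases$laterality[i], "_", cases$view[i],
      ".tiff"
    ))
    tiff::writeTIFF(cases$image[[i]], file.path(dir, rel),
                    bits.per.sample = 16L)
    b <- cases$boxes[[i]]
    base <- tibble(
      patient_id = cases$patient_id[i], laterality = cases$laterality[i],
      view = cases$view[i], label = cases$label[i], tier = cases$tier[i],
      image_path = rel
    )
    rows[[i]] <- if (nrow(b) == 0) {
      mutate(base, x0 = NA_integer_, y0 = NA_integer_,
             x1 = NA_integer_, y1 = NA_integer_)
    } else {
      bind_cols(base[rep(1, nrow(b)), ], b)
    }
  }
  manifest <- bind_rows(rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `manifest.csv` and the image files.
#' @return Cohort tibble with `image` and `boxes` list-columns.
#' @export
read_cohort <- function(dir) {
  manifest <- as_tibble(utils::read.csv(file.path(dir, "manifest.csv"),
                                        stringsAsFactors = FALSE))
  keys <- manifest |>
    dplyr::distinct(.data$patient_id, .data$laterality, .data$view,
                    .data$label, .data$tier, .data$image_path)
  keys$image <- purrr::map(keys$image_path,
                           ~ read_gray_image(file.path(dir, .x)))
  keys$boxes <- purrr::pmap(
    list(keys$patient_id, keys$laterality, keys$view),
    function(p, l, v) {
      b <- filter(manifest, .data$patient_id == p, .data$laterality == l,
                  .data$view == v, !is.na(.data$x0))
      if (nrow(b) == 0) empty_boxes() else boxes(b$x0, b$y0, b$x1, b$y1)
    }
  )
  select(keys, -"image_path")
}

#' Write / read a patch dataset
#'
#' Serializes patch samples as 16-bit TIFF crops plus a CSV index
#' (`case_id`, box coordinates, `label`, `overlap_fraction`); the pair
#' round-trips at 16-bit pixel precision.
#'
#' @param samples Patch tibble from [build_patch_dataset()].
#' @param dir Output directory.
#' @return The index tibble, invisibly (write) or the patch tibble (read).
#' @export
write_patch_dataset <- function(samples, dir) {
  dir.create(file.path(dir, "patches"), recursive = TRUE,
             showWarnings = FALSE)
  idx <- samples |>
    mutate(patch_path = file.path("patches", sprintf(
      "%s_%d_%d.tiff", .data$case_id, .data$y0, .data$x0
    ))) |>
    select(-"pixels")
  for (i in seq_len(nrow(samples))) {
    tiff::writeTIFF(samples$pixels[[i]], file.path(dir, idx$patch_path[i]),
                    bits.per.sample = 16L)
  }
  utils::write.csv(idx, file.path(dir, "index.csv"), row.names = FALSE)
  invisible(idx)
}

#' @rdname write_patch_dataset
#' @export
read_patch_dataset <- function(dir) {
  idx <- as_tibble(utils::read.csv(file.path(dir, "index.csv"),
                                   stringsAsFactors = FALSE))
  idx$pixels <- purrr::map(idx$patch_path,
                           ~ read_gray_image(file.path(dir, .x)))
  select(idx, -"patch_path") |>
    dplyr::relocate("pixels", .after = "y1")
}

#' Save / load model weights
#'
#' Weights and configuration are stored as JSON (text, portable across
#' platforms); numeric precision is preserved to full double resolution.
#'
#' @param model A `curri_backbone`.
#' @param path File path.
#' @return `save_backbone()` returns `path` invisibly; `load_backbone()`
#'   the model.
#' @export
save_backbone <- function(model, path) {
  payload <- list(
    config = list(architecture = model$config$architecture,
                  n_classes = model$config$n_classes,
                  channels = model$config$channels),
    conv = purrr::map(model$conv, function(l) {
      list(W = as.vector(l$W), dim = dim(l$W), b = l$b)
    }),
    head = list(W = as.vector(model$head$W), dim = dim(model$head$W),
                b = model$head$b)
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_backbone
#' @export
load_backbone <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- backbone_config(p$config$architecture, p$config$n_classes,
                         p$config$channels)
  conv <- purrr::map(seq_along(cfg$channels), function(i) {
    l <- if (is.data.frame(p$conv)) p$conv[i, ] else p$conv[[i]]
    list(W = matrix(unlist(l$W), unlist(l$dim)[1], unlist(l$dim)[2]),
         b = as.numeric(unlist(l$b)))
  })
  head <- list(W = matrix(unlist(p$head$W), p$head$dim[1], p$head$dim[2]),
               b = as.numeric(unlist(p$head$b)))
  structure(list(config = cfg, conv = conv, head = head),
            class = "curri_backbone")
}
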