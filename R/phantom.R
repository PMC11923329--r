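#' Configuration for the phantom screening cohort generator
#'
#' The generator emulates the structure of a balanced opportunistic-screening
#' cohort: every patient contributes craniocaudal (CC) and mediolateral
#' oblique (MLO) views of both breasts; half the patients (by default) carry
#' pathology-confirmed cancer, planted as one or more bright lesion blobs with
#' tight ground-truth bounding boxes recorded per view. Images are breast-like
#' bright foreground anchored to the chest-wall edge on a near-zero
#' background, emitted at a native size larger than the network input so the
#' cropping stage has real work to do.
#'
#' @param image_height,image_width Native image size in pixels.
#' @param n_patients Number of patients in the cohort.
#' @param cancer_fraction Fraction of patients with cancer, in `[0, 1]`.
#' @param lesion_count_range Integer interval `c(min, max)` of lesions per
#'   affected breast.
#' @param lesion_radius_range Pixel interval `c(min, max)` of lesion radii.
#' @param lesion_contrast Additive intensity offset of a lesion above the
#'   breast foreground, on the `[0, 1]` scale. The default gives a clearly
#'   supra-threshold signal; lower it for a hard mode.
#' @param background_noise_sd Gaussian pixel-noise standard deviation.
#' @param breast_shape `"half-disc"` or `"ellipse"` foreground silhouette.
#' @param foreground_level Mean breast-tissue intensity.
#' @param seed Master seed; each patient draws from an RNG stream derived
#'   from it, so growing the cohort never reshuffles existing patients.
#' @return A `phantom_config` list, validated.
#' @export
phantom_config <- function(image_height = 1536L, image_width = 1280L,
                           n_patients = 60L, cancer_fraction = 0.5,
                           lesion_count_range = c(1L, 3L),
                           lesion_radius_range = c(40L, 90L),
                           lesion_contrast = 0.35,
                           background_noise_sd = 0.008,
                           breast_shape = c("half-disc", "ellipse"),
                           foreground_level = 0.45,
                           seed = 42L) {
  breast_shape <- match.arg(breast_shape)
  cfg <- structure(list(
    image_height = as.integer(image_height),
    image_width = as.integer(image_width),
    n_patients = as.integer(n_patients),
    cancer_fraction = cancer_fraction,
    lesion_count_range = as.integer(lesion_count_range),
    lesion_radius_range = as.integer(lesion_radius_range),
    lesion_contrast = lesion_contrast,
    background_noise_sd = background_noise_sd,
    breast_shape = breast_shape,
    foreground_level = foreground_level,
    seed = as.integer(seed)
  ), class = "phantom_config")
  validate_phantom_config(cfg)
  cfg
}

validate_phantom_config <- function(cfg) {
  if (cfg$cancer_fraction < 0 || cfg$cancer_fraction > 1) {
    abort("cancer_fraction must lie in [0, 1]")
  }
  if (any(cfg$lesion_radius_range <= 0) ||
      max(cfg$lesion_radius_range) >= min(cfg$image_height, cfg$image_width) / 2) {
    abort("lesion_radius_range must be positive and smaller than min(image dims)/2")
  }
  if (cfg$lesion_count_range[1] < 1 ||
      cfg$lesion_count_range[2] < cfg$lesion_count_range[1]) {
    abort("lesion_count_range must be an increasing interval with min >= 1")
  }
  if (cfg$image_height < 8 || cfg$image_width < 8) abort("image too small")
  invisible(cfg)
}

# Per-patient RNG stream derived from the master seed. Keeps patient i's
# draws independent of cohort size.
patient_seed <- function(master_seed, patient_index) {
  as.integer((as.double(master_seed) * 48271 + patient_index * 16807) %%
               2147483647)
}

# Evenly interleaved positive assignment: exactly round(f * n) positives for
# any prefix-stable pattern (telescoping sum of rounded cumulative counts).
is_positive_patient <- function(idx, cancer_fraction) {
  round(idx * cancer_fraction) > round((idx - 1) * cancer_fraction)
}

breast_foreground_mask <- function(cfg) {
  h <- cfg$image_height; w <- cfg$image_width
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  cy <- h / 2
  if (cfg$breast_shape == "half-disc") {
    r <- 0.92 * min(h / 2, w)
    ((xx - 1)^2 + (yy - cy)^2) <= r^2
  } else {
    a <- 0.80 * w
    b <- 0.90 * h / 2
    ((xx - 1) / a)^2 + ((yy - cy) / b)^2 <= 1
  }
}

# Draw lesion parameters (relative center + radius) that fit inside the
# foreground with margin; bounded retries, then an informative error.
draw_lesions <- function(cfg, fg_mask, n_lesions) {
  h <- nrow(fg_mask); w <- ncol(fg_mask)
  lesions <- vector("list", n_lesions)
  for (k in seq_len(n_lesions)) {
    radius <- runif(1, cfg$lesion_radius_range[1], cfg$lesion_radius_range[2])
    placed <- FALSE
    for (try in 1:200) {
      cx <- runif(1, radius + 1, w - radius - 1)
      cy <- runif(1, radius + 1, h - radius - 1)
      # all four cardinal extremes must sit on tissue
      pts <- rbind(c(cy, cx - radius), c(cy, cx + radius),
                   c(cy - radius, cx), c(cy + radius, cx))
      idx <- cbind(pmin(pmax(round(pts[, 1]), 1), h),
                   pmin(pmax(round(pts[, 2]), 1), w))
      if (all(fg_mask[idx])) {
        lesions[[k]] <- list(cx = cx / w, cy = cy / h, radius = radius)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      abort(paste0(
        "lesion placement failed: a lesion of radius ", round(radius),
        " px cannot fit inside the breast foreground; ",
        "check lesion_radius_range against image_height/image_width"
      ))
    }
  }
  lesions
}

# Render one view: foreground + noise, lesions as supra-threshold discs whose
# tight pixel bounding boxes are recorded.
render_view <- function(cfg, lesions, jitter = c(0, 0), radius_jitter = 1) {
  h <- cfg$image_height; w <- cfg$image_width
  fg <- breast_foreground_mask(cfg)
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  img <- matrix(rnorm(h * w, 0, cfg$background_noise_sd), h, w)
  # gentle radial shading keeps the foreground below the lesion level
  shade <- 1 - 0.15 * sqrt(((xx - 1) / w)^2 + ((yy - h / 2) / h)^2)
  img[fg] <- cfg$foreground_level * shade[fg] +
    rnorm(sum(fg), 0, cfg$background_noise_sd)
  gt <- empty_boxes()
  lesion_level <- cfg$foreground_level + cfg$lesion_contrast
  for (les in lesions) {
    cx <- les$cx * w + jitter[1]
    cy <- les$cy * h + jitter[2]
    r <- les$radius * radius_jitter
    disc <- ((xx - cx)^2 + (yy - cy)^2) <= r^2
    if (!any(disc)) next
    img[disc] <- lesion_level
    cols <- which(apply(disc, 2, any)); rows <- which(apply(disc, 1, any))
    gt <- bind_rows(gt, boxes(
      x0 = min(cols) - 1L, y0 = min(rows) - 1L,
      x1 = max(cols), y1 = max(rows)
    ))
  }
  list(image = pmin(pmax(img, 0), 1), boxes = gt)
}

#' Generate one phantom view
#'
#' Renders a single mammographic view for one breast: breast-shaped bright
#' foreground anchored to the left (chest-wall) edge, near-zero background,
#' and, for positive cases, lesion discs at `foreground + lesion_contrast`
#' with their tight bounding boxes. The CC and MLO views of the same breast
#' share lesion parameters under a mild geometric jitter, which is what
#' `lesions` carries between calls.
#'
#' @param config A [phantom_config()].
#' @param patient_id,laterality,view Case identity (`"L"/"R"`, `"CC"/"MLO"`).
#' @param seed RNG seed for this view's noise and jitter.
#' @param lesions List of lesion parameter lists (`cx`, `cy` relative center,
#'   `radius` px) or `NULL` for a negative case.
#' @return One-row tibble: a view case with `image` and `boxes` list-columns,
#'   `label` and `tier` columns.
#' @export
generate_case <- function(config, patient_id, laterality, view, seed,
                          lesions = NULL) {
  validate_phantom_config(config)
  set.seed(as.integer(seed))
  positive <- length(lesions) > 0
  jitter <- if (view == "MLO" && positive) {
    c(runif(1, -0.02, 0.02) * config$image_width,
      runif(1, -0.02, 0.02) * config$image_height)
  } else c(0, 0)
  radius_jitter <- if (view == "MLO" && positive) runif(1, 0.95, 1.05) else 1
  rendered <- render_view(config, lesions %||% list(), jitter, radius_jitter)
  tibble(
    patient_id = as.character(patient_id),
    laterality = laterality,
    view = view,
    label = if (positive) "positive" else "negative",
    tier = "weak",
    image = list(rendered$image),
    boxes = list(rendered$boxes)
  )
}

#' Generate a phantom screening cohort
#'
#' Emits CC and MLO views of both breasts for every patient. A deterministic
#' interleaving makes the positive fraction exact up to rounding for every
#' cohort size; positive patients carry the same lesion(s) in both views of
#' the affected breast. All cases start at tier `"weak"`; see
#' [assign_annotation_tiers()].
#'
#' @param config A [phantom_config()].
#' @return Tibble of view cases, `4 * n_patients` rows
#'   (2 breasts x 2 views), grouped by patient.
#' @export
generate_cohort <- function(config) {
  validate_phantom_config(config)
  if (config$n_patients < 2) abort("n_patients must be >= 2")
  fg <- breast_foreground_mask(config)
  out <- vector("list", config$n_patients)
  for (i in seq_len(config$n_patients)) {
    pid <- sprintf("P%04d", i)
    pseed <- patient_seed(config$seed, i)
    set.seed(pseed)
    positive <- is_positive_patient(i, config$cancer_fraction)
    affected <- if (positive) sample(c("L", "R"), 1) else NA_character_
    lesions <- if (positive) {
      n_les <- sample(seq(config$lesion_count_range[1],
                          config$lesion_count_range[2]), 1)
      draw_lesions(config, fg, n_les)
    } else NULL
    cases <- list()
    for (lat in c("L", "R")) {
      for (vw in c("CC", "MLO")) {
        case_seed <- patient_seed(pseed, match(lat, c("L", "R")) * 2 +
                                    match(vw, c("CC", "MLO")))
        les <- if (positive && identical(lat, affected)) lesions else NULL
        cases[[length(cases) + 1]] <-
          generate_case(config, pid, lat, vw, case_seed, les)
      }
    }
    out[[i]] <- bind_rows(cases)
  }
  bind_rows(out)
}

#' Assign strong/weak annotation tiers to a cohort
#'
#' Marks exactly `round(strong_fraction * n_patients)` patients as strong
#' (bounding boxes available to training consumers); the rest stay weak
#' (image-level label only). Selection is random, stratified by the patient's
#' label, and reproducible under `seed`. This is the lever behind the
#' baseline / curriculum-20 / curriculum-40 / curriculum-100 regimes.
#'
#' @param cases Cohort tibble from [generate_cohort()].
#' @param strong_fraction Proportion of patients with box supervision.
#' @param seed RNG seed for the stratified draw.
#' @return The cohort with its `tier` column set.
#' @export
assign_annotation_tiers <- function(cases, strong_fraction, seed = 1L) {
  if (strong_fraction < 0 || strong_fraction > 1) {
    abort("strong_fraction must lie in [0, 1]")
  }
  pat <- cases |>
    group_by(.data$patient_id) |>
    summarise(label = if (any(.data$label == "positive")) "positive" else "negative",
              .groups = "drop")
  n_total <- nrow(pat)
  n_strong <- round(strong_fraction * n_total)
  # largest-remainder apportionment across label strata hits n_strong exactly
  strata <- split(pat$patient_id, pat$label)
  quota <- vapply(strata, function(p) strong_fraction * length(p), numeric(1))
  base <- floor(quota)
  rem <- n_strong - sum(base)
  if (rem > 0) {
    order_frac <- order(quota - base, decreasing = TRUE)
    base[order_frac[seq_len(rem)]] <- base[order_frac[seq_len(rem)]] + 1
  } else if (rem < 0) {
    order_frac <- order(quota - base, decreasing = FALSE)
    base[order_frac[seq_len(-rem)]] <- base[order_frac[seq_len(-rem)]] - 1
  }
  set.seed(as.integer(seed))
  strong_ids <- unlist(purrr::map2(strata, base, function(ids, k) {
    if (k <= 0) character(0) else sample(ids, min(k, length(ids)))
  }), use.names = FALSE)
  mutate(cases, tier = ifelse(.data$patient_id %in% strong_ids,
                              "strong", "weak"))
}
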