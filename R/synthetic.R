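#' Settings of the two-class synthetic nucleus generator
#'
#' Generates elliptical "nuclei" on a cleared (white) background with three
#' texture ingredients: a smooth low-frequency chromatin field, a Poisson
#' point process of dark chromatin clumps, and i.i.d. Gaussian pixel noise.
#' The injured ("AKI-like", group 1) class gets stronger pixel noise, more
#' clumps and a small upward mean shift than the control-like class, which
#' moves every texture feature in the direction observed for injured
#' proximal-tubule nuclei: ASM and IDM down; CON, SA, SVAR and the three
#' wavelet energies up. The direction of COR is deliberately left
#' unconstrained.
#'
#' @param n_per_class ROIs per class (default 700, i.e. a 1400-ROI study).
#' @param n_animals_per_class Animals per class (default 7); ROIs are
#'   assigned to animals round-robin, 100 per animal at the defaults.
#' @param patch_size Side of the square patch in pixels.
#' @param major_axis_range,minor_axis_range Semi-axis ranges (pixels) of the
#'   random ellipse.
#' @param base_mean Mean interior intensity (8-bit scale).
#' @param base_amplitude SD of the smooth chromatin field.
#' @param smoothness Gaussian blur sigma (pixels) of the chromatin field.
#' @param noise_sd_control,noise_sd_aki Pixel-noise SD per class; the AKI
#'   value must exceed the control value.
#' @param clump_rate_control,clump_rate_aki Expected dark clumps per nucleus
#'   (Poisson); the AKI rate must exceed the control rate.
#' @param clump_darkening Peak intensity drop at a clump center.
#' @param clump_radius Gaussian radius (pixels) of a clump profile.
#' @param mean_shift_aki Intensity offset added to the AKI class (>= 0).
#' @param seed Integer seed; the full dataset is reproducible from
#'   (config, seed).
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_per_class = 700L,
                             n_animals_per_class = 7L,
                             patch_size = 96L,
                             major_axis_range = c(24, 38),
                             minor_axis_range = c(16, 28),
                             base_mean = 110,
                             base_amplitude = 18,
                             smoothness = 6,
                             noise_sd_control = 4,
                             noise_sd_aki = 7,
                             clump_rate_control = 0.2,
                             clump_rate_aki = 6,
                             clump_darkening = 70,
                             clump_radius = 4,
                             mean_shift_aki = 12,
                             seed = 20260101L) {
  cfg <- list(n_per_class = as.integer(n_per_class),
              n_animals_per_class = as.integer(n_animals_per_class),
              patch_size = as.integer(patch_size),
              major_axis_range = major_axis_range,
              minor_axis_range = minor_axis_range,
              base_mean = base_mean, base_amplitude = base_amplitude,
              smoothness = smoothness,
              noise_sd_control = noise_sd_control,
              noise_sd_aki = noise_sd_aki,
              clump_rate_control = clump_rate_control,
              clump_rate_aki = clump_rate_aki,
              clump_darkening = clump_darkening,
              clump_radius = clump_radius,
              mean_shift_aki = mean_shift_aki,
              seed = as.integer(seed))
  if (cfg$n_per_class < 1L) stop("n_per_class must be >= 1", call. = FALSE)
  if (cfg$noise_sd_aki < cfg$noise_sd_control) {
    stop("noise_sd_aki must be >= noise_sd_control", call. = FALSE)
  }
  if (cfg$clump_rate_aki < cfg$clump_rate_control) {
    stop("clump_rate_aki must be >= clump_rate_control", call. = FALSE)
  }
  if (cfg$mean_shift_aki < 0) stop("mean_shift_aki must be >= 0",
                                   call. = FALSE)
  structure(cfg, class = "synthetic_config")
}

#' Null (no-effect) variant of a synthetic configuration
#'
#' Sets the AKI-class noise SD, clump rate and mean shift equal to the
#' control values, so both classes are drawn from the same distribution and
#' any classifier's expected test AUC is 0.5.
#'
#' @param config A [synthetic_config()].
#' @return The modified `synthetic_config`.
#' @export
synthetic_null_config <- function(config = synthetic_config()) {
  config$noise_sd_aki <- config$noise_sd_control
  config$clump_rate_aki <- config$clump_rate_control
  config$mean_shift_aki <- 0
  config
}

# Separable Gaussian blur with replicated edges, as a band matrix applied to
# rows and columns; matrices are memoized per (n, sigma).
blur_cache <- new.env(parent = emptyenv())

blur_matrix <- function(n, sigma) {
  key <- paste0(n, "_", sigma)
  if (!is.null(blur_cache[[key]])) return(blur_cache[[key]])
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  M <- matrix(0, n, n)
  idx <- seq_len(n)
  for (o in -r:r) {
    src <- pmin(pmax(idx + o, 1L), n)
    M[cbind(idx, src)] <- M[cbind(idx, src)] + k[o + r + 1L]
  }
  blur_cache[[key]] <- M
  M
}

gaussian_blur <- function(x, sigma) {
  Mr <- blur_matrix(nrow(x), sigma)
  Mc <- blur_matrix(ncol(x), sigma)
  Mr %*% x %*% t(Mc)
}

#' Generate one synthetic nucleus image and mask
#'
#' Draws from the current RNG state (seed it upstream, e.g. via
#' [generate_dataset()] or `set.seed()`). The interior intensity is the
#' smooth chromatin field blended toward a fixed dark clump level where
#' clumps sit, plus i.i.d. pixel noise, clipped to 8 bits; the exterior is
#' cleared to white (255), mimicking an ROI isolated from its micrograph.
#'
#' @param config A [synthetic_config()].
#' @param class_label 0 = control-like, 1 = AKI-like.
#' @param min_area Minimum mask area in pixels; smaller draws are retried a
#'   bounded number of times.
#' @return List with `image` (integer matrix, 0..255) and `mask` (logical
#'   matrix).
#' @export
generate_nucleus <- function(config = synthetic_config(), class_label,
                             min_area = 64L) {
  stopifnot(class_label %in% c(0L, 1L))
  ps <- config$patch_size
  ctr <- (ps + 1) / 2
  max_semi <- ps / 2 - 3
  mask <- NULL
  for (try in 1:20) {
    a <- stats::runif(1, config$major_axis_range[1],
                      min(config$major_axis_range[2], max_semi))
    b <- stats::runif(1, config$minor_axis_range[1],
                      min(config$minor_axis_range[2], max_semi))
    th <- stats::runif(1, 0, pi)
    jit <- stats::runif(2, -2, 2)
    dx <- outer(rep(1, ps), seq_len(ps) - ctr - jit[2])
    dy <- outer(seq_len(ps) - ctr - jit[1], rep(1, ps))
    u <- (dx * cos(th) + dy * sin(th)) / a
    v <- (-dx * sin(th) + dy * cos(th)) / b
    mask <- u^2 + v^2 <= 1
    if (sum(mask) >= min_area) break
    mask <- NULL
  }
  if (is.null(mask)) {
    stop("could not generate a nucleus mask with area >= ", min_area,
         call. = FALSE)
  }

  aki <- class_label == 1L
  noise_sd <- if (aki) config$noise_sd_aki else config$noise_sd_control
  clump_rate <- if (aki) config$clump_rate_aki else config$clump_rate_control
  shift <- if (aki) config$mean_shift_aki else 0

  field <- gaussian_blur(matrix(stats::rnorm(ps * ps), ps, ps),
                         config$smoothness)
  field <- field / stats::sd(field)
  img <- config$base_mean + shift + config$base_amplitude * field

  # chromatin clumps: each clump pulls intensity toward a fixed dark
  # "condensed chromatin" level via a saturating Gaussian occupancy, so
  # overlapping clumps never darken below base - clump_darkening and the
  # dark mode stays inside the ROI's own intensity range
  n_clumps <- stats::rpois(1, clump_rate)
  if (n_clumps > 0) {
    inside <- which(mask)
    pick <- inside[pmax(1L, ceiling(stats::runif(n_clumps) * length(inside)))]
    rows <- (pick - 1) %% ps + 1
    cols <- (pick - 1) %/% ps + 1
    depth <- stats::runif(n_clumps, 0.85, 1)
    gx <- outer(rep(1, ps), seq_len(ps))
    gy <- outer(seq_len(ps), rep(1, ps))
    vacancy <- matrix(1, ps, ps)
    for (ci in seq_len(n_clumps)) {
      d2 <- (gy - rows[ci])^2 + (gx - cols[ci])^2
      vacancy <- vacancy *
        (1 - depth[ci] * exp(-d2 / (2 * config$clump_radius^2)))
    }
    occ <- 1 - vacancy
    floor_level <- config$base_mean + shift - config$clump_darkening
    img <- (1 - occ) * img + occ * floor_level
  }

  img <- img + stats::rnorm(ps * ps, sd = noise_sd)
  img <- round(pmin(pmax(img, 0), 255))
  img[!mask] <- 255
  storage.mode(img) <- "integer"
  list(image = img, mask = mask)
}

#' Generate a full two-class synthetic dataset on disk
#'
#' Writes `images/<roi_id>.png`, `masks/<roi_id>_mask.png` and
#' `manifest.csv` (schema `roi_id,image_path,mask_path,group,animal_id`)
#' under `dir`. Control ROIs (group 0) come first, then AKI ROIs (group 1);
#' within a class, ROIs are dealt to the animals round-robin. The whole
#' dataset is bit-reproducible from (config, seed).
#'
#' @param config A [synthetic_config()].
#' @param dir Output directory (created if needed).
#' @return The manifest data.frame, invisibly.
#' @export
generate_dataset <- function(config = synthetic_config(),
                             dir = "synthetic_data") {
  dir.create(file.path(dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir,
                             call. = FALSE)
  set.seed(config$seed)
  n <- config$n_per_class
  na <- config$n_animals_per_class
  rows <- vector("list", 2L * n)
  idx <- 0L
  for (grp in c(0L, 1L)) {
    prefix <- if (grp == 0L) "C" else "A"
    for (i in seq_len(n)) {
      idx <- idx + 1L
      roi_id <- sprintf("roi_%s%04d", prefix, i)
      nuc <- generate_nucleus(config, grp)
      img_rel <- file.path("images", paste0(roi_id, ".png"))
      msk_rel <- file.path("masks", paste0(roi_id, "_mask.png"))
      write_image_png(nuc$image, file.path(dir, img_rel))
      write_image_png(nuc$mask, file.path(dir, msk_rel))
      rows[[idx]] <- data.frame(
        roi_id = roi_id, image_path = img_rel, mask_path = msk_rel,
        group = grp,
        animal_id = sprintf("%s%d", prefix, (i - 1L) %% na + 1L),
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  manifest$image_path <- file.path(dir, manifest$image_path)
  manifest$mask_path <- file.path(dir, manifest$mask_path)
  invisible(manifest)
}
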