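#' Read a micrograph from disk
#'
#' Reads a PNG or TIFF image and returns integer intensities on the 8-bit
#' scale. Grayscale images come back as a `height x width` integer matrix;
#' RGB images as a `height x width x 3` array (any alpha channel is dropped).
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return Integer matrix or 3-channel array with values in `[0, 255]`.
#' @seealso [rgb_to_gray()], [load_roi()]
#' @export
read_image <- function(path) {
  if (!file.exists(path)) {
    stop("image file not found: ", path, call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format '.", ext, "' (PNG and TIFF are supported): ",
         path, call. = FALSE)
  )
  if (length(dim(img)) == 3L && dim(img)[3] == 4L) {
    img <- img[, , 1:3, drop = FALSE]
  }
  if (length(dim(img)) == 3L && dim(img)[3] == 1L) {
    img <- img[, , 1L]
  }
  out <- round(img * 255)
  storage.mode(out) <- "integer"
  out
}

#' Write an 8-bit image to disk as PNG
#'
#' @param pixels Integer matrix (grayscale) with values in `[0, 255]`, or a
#'   logical matrix (written as 0/255 binary mask).
#' @param path Output path ending in `.png`.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(pixels, path) {
  if (is.logical(pixels)) {
    pixels <- ifelse(pixels, 255L, 0L)
    dim(pixels) <- dim(pixels)
  }
  stopifnot(is.matrix(pixels) || length(dim(pixels)) == 3L)
  png::writePNG(pixels / 255, target = path)
  invisible(path)
}

#' Convert an RGB micrograph to 8-bit grayscale
#'
#' Uses ITU-R BT.601 luma weights: `round(0.299 R + 0.587 G + 0.114 B)`.
#' Equal-channel pixels are fixed points, so an already-gray RGB image is
#' unchanged.
#'
#' @param pixels A `height x width x 3` integer array, or a grayscale matrix
#'   (returned unchanged).
#' @return Integer matrix of luminance values.
#' @export
rgb_to_gray <- function(pixels) {
  if (is.matrix(pixels)) {
    return(pixels)
  }
  d <- dim(pixels)
  if (length(d) != 3L || d[3] != 3L) {
    stop("expected a 2D grayscale matrix or a 3-channel RGB array, got dims: ",
         paste(d, collapse = " x "), call. = FALSE)
  }
  g <- round(0.299 * pixels[, , 1L] + 0.587 * pixels[, , 2L] +
               0.114 * pixels[, , 3L])
  storage.mode(g) <- "integer"
  g
}

#' Construct a gray-level ROI patch
#'
#' A `gray_patch` holds a rectangular crop of grayscale intensities together
#' with an aligned boolean mask marking which pixels belong to the nucleus.
#' All texture computations only ever use masked-in pixels (or, for the
#' wavelet transform, a mean-filled version of the rectangle).
#'
#' @param pixels Integer matrix of intensities.
#' @param mask Logical matrix, same shape; `TRUE` = inside the ROI. Defaults
#'   to all-`TRUE`.
#' @param levels Number of gray levels the intensities are expressed in
#'   (256 for raw 8-bit data; `G` after [quantize_gray()]).
#' @param origin Zero-based `(row, col)` of the crop's top-left corner in the
#'   source image.
#' @return An object of class `gray_patch`.
#' @export
gray_patch <- function(pixels, mask = NULL, levels = 256L,
                       origin = c(0L, 0L)) {
  stopifnot(is.matrix(pixels))
  storage.mode(pixels) <- "integer"
  if (is.null(mask)) {
    mask <- matrix(TRUE, nrow(pixels), ncol(pixels))
  }
  if (!is.logical(mask)) {
    mask <- mask != 0
    dim(mask) <- dim(pixels)
  }
  if (!identical(dim(mask), dim(pixels))) {
    stop("mask dimensions (", paste(dim(mask), collapse = " x "),
         ") do not match pixel dimensions (",
         paste(dim(pixels), collapse = " x "), ")", call. = FALSE)
  }
  if (!any(mask)) {
    stop("ROI mask is empty: no masked-in pixels", call. = FALSE)
  }
  if (any(pixels < 0L) || any(pixels > levels - 1L)) {
    stop("intensities outside [0, levels-1]", call. = FALSE)
  }
  structure(
    list(pixels = pixels, mask = mask, levels = as.integer(levels),
         origin = as.integer(origin)),
    class = "gray_patch"
  )
}

#' @export
print.gray_patch <- function(x, ...) {
  cat("<gray_patch> ", nrow(x$pixels), "x", ncol(x$pixels),
      " (", sum(x$mask), " masked-in px, ", x$levels, " levels, origin ",
      x$origin[1], ",", x$origin[2], ")\n", sep = "")
  invisible(x)
}

#' Read the ROI manifest CSV
#'
#' The manifest lists one nucleus ROI per row with columns
#' `roi_id,image_path,mask_path,group,animal_id`; `group` is 1 for injured
#' (AKI) and 0 for control. Relative image/mask paths are resolved against
#' the manifest's directory.
#'
#' @param path Path to the manifest CSV.
#' @return A data.frame of ROI records.
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("roi_id", "image_path", "mask_path", "group", "animal_id")
  missing <- setdiff(required, names(m))
  if (length(missing)) {
    stop("manifest is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  m$roi_id <- as.character(m$roi_id)
  m$animal_id <- as.character(m$animal_id)
  if (!all(m$group %in% c(0L, 1L))) {
    stop("manifest group labels must be 0 (control) or 1 (AKI)",
         call. = FALSE)
  }
  base <- dirname(path)
  for (col in c("image_path", "mask_path")) {
    rel <- !grepl("^(/|[A-Za-z]:)", m[[col]])
    m[[col]][rel] <- file.path(base, m[[col]][rel])
  }
  m
}

#' Load one ROI as a gray patch
#'
#' Reads the image and its binary mask (any nonzero mask pixel is inside the
#' ROI), converts RGB to grayscale, crops both to the mask's bounding box and
#' optionally quantizes the gray levels.
#'
#' @param record One manifest row (list or single-row data.frame) with at
#'   least `image_path` and `mask_path`.
#' @param quantization Optional [quantization_config()]; if supplied the
#'   returned patch is quantized.
#' @param min_pixels Minimum number of masked-in pixels an ROI must have.
#' @return A [gray_patch()] cropped to the mask bounding box, with `origin`
#'   recording the crop position in the source image.
#' @export
load_roi <- function(record, quantization = NULL, min_pixels = 8L) {
  img <- rgb_to_gray(read_image(record$image_path))
  mraw <- read_image(record$mask_path)
  if (length(dim(mraw)) == 3L) {
    mraw <- apply(mraw, c(1, 2), max)
  }
  if (!identical(dim(mraw), dim(img))) {
    stop("mask dimensions do not match image dimensions for ROI ",
         record$roi_id %||% record$mask_path, call. = FALSE)
  }
  mask <- mraw != 0
  if (!any(mask)) {
    stop("empty mask for ROI ", record$roi_id %||% record$mask_path,
         call. = FALSE)
  }
  if (sum(mask) < min_pixels) {
    stop("ROI has fewer than ", min_pixels, " masked-in pixels",
         call. = FALSE)
  }
  rr <- range(which(rowSums(mask) > 0))
  cc <- range(which(colSums(mask) > 0))
  patch <- gray_patch(img[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE],
                      mask[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE],
                      levels = 256L,
                      origin = c(rr[1] - 1L, cc[1] - 1L))
  if (!is.null(quantization)) {
    patch <- quantize_gray(patch, quantization$levels, quantization$strategy)
  }
  patch
}

#' Gray-level quantization settings
#'
#' @param levels Number of gray levels `G`; a power of two in `{8, ..., 256}`.
#'   Default 64, the 6-bit dynamics customary in texture-analysis tools.
#' @param strategy `"minmax"` (linear rescale of the ROI's own min..max to
#'   `0..G-1`; illumination-invariant), `"bitshift"` (drop low bits of the
#'   8-bit value; preserves absolute intensity) or `"sigma3"` (clip to the
#'   masked mean plus/minus 3 SD, then min-max rescale; robust to outliers).
#' @return A list of class `quantization_config`.
#' @export
quantization_config <- function(levels = 64L,
                                strategy = c("minmax", "bitshift", "sigma3")) {
  strategy <- match.arg(strategy)
  levels <- as.integer(levels)
  if (!(levels %in% c(8L, 16L, 32L, 64L, 128L, 256L))) {
    stop("levels must be a power of two in {8, 16, 32, 64, 128, 256}",
         call. = FALSE)
  }
  structure(list(levels = levels, strategy = strategy),
            class = "quantization_config")
}

#' Quantize a gray patch to G levels
#'
#' Statistics driving the mapping (min, max, mean, SD) are computed over
#' masked-in pixels only; the same monotone map is then applied to every
#' pixel in the rectangle (clamped to `[0, G-1]`).
#'
#' @param patch A [gray_patch()].
#' @param levels Target number of gray levels `G`.
#' @param strategy See [quantization_config()].
#' @return A new `gray_patch` with `levels = G`.
#' @export
quantize_gray <- function(patch, levels = 64L,
                          strategy = c("minmax", "bitshift", "sigma3")) {
  strategy <- match.arg(strategy)
  cfg <- quantization_config(levels, strategy)  # validates levels
  G <- cfg$levels
  v <- patch$pixels
  inside <- v[patch$mask]
  q <- switch(strategy,
    minmax = {
      lo <- min(inside); hi <- max(inside)
      if (hi == lo) {
        array(0L, dim(v))
      } else {
        round((v - lo) / (hi - lo) * (G - 1))
      }
    },
    bitshift = {
      if (patch$levels != 256L) {
        stop("bitshift quantization requires raw 8-bit input", call. = FALSE)
      }
      v %/% (2L^(8L - as.integer(log2(G))))
    },
    sigma3 = {
      m <- mean(inside); s <- stats::sd(inside)
      if (is.na(s) || s == 0) {
        array(0L, dim(v))
      } else {
        lo <- m - 3 * s; hi <- m + 3 * s
        round((pmin(pmax(v, lo), hi) - lo) / (hi - lo) * (G - 1))
      }
    }
  )
  q <- pmin(pmax(q, 0L), G - 1L)
  q <- array(as.integer(q), dim(v))
  gray_patch(q, patch$mask, levels = G, origin = patch$origin)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
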