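#' Wavelet energy settings
#'
#' @param on Which intensities the transform sees: `"raw"` (default; the
#'   unquantized 8-bit grayscale patch — gray-level quantization is a
#'   GLCM-specific step) or `"quantized"`.
#' @param denominator Normalizer `n` of the energy `E = sum(d^2) / n`:
#'   `"coefficients"` (default; the number of included subband coefficients,
#'   i.e. mean energy per coefficient) or `"pixels"` (the ROI pixel count,
#'   which scales every energy down by about 4).
#' @return A list of class `wavelet_config`.
#' @export
wavelet_config <- function(on = c("raw", "quantized"),
                           denominator = c("coefficients", "pixels")) {
  structure(list(on = match.arg(on),
                 denominator = match.arg(denominator)),
            class = "wavelet_config")
}

pad_even <- function(x) {
  if (nrow(x) %% 2L == 1L) x <- rbind(x, x[nrow(x), , drop = FALSE])
  if (ncol(x) %% 2L == 1L) x <- cbind(x, x[, ncol(x), drop = FALSE])
  x
}

#' First-level 2D Haar decomposition of a masked patch
#'
#' Pixels outside the mask are filled with the rounded mean of the masked-in
#' pixels, odd dimensions are padded by edge replication, and the orthonormal
#' Haar analysis is applied to non-overlapping 2x2 blocks
#' `[[a, b], [c, d]]` (b right of a, c below a):
#' `LL = (a+b+c+d)/2`, `LH = (a-b+c-d)/2`, `HL = (a+b-c-d)/2`,
#' `HH = (a-b-c+d)/2`.
#'
#' Subband naming: first letter = filter along y (rows), second = filter
#' along x (columns), so LH is the horizontal-detail band (high-pass across
#' columns) and HL the vertical-detail band. A coefficient is `included`
#' iff its 2x2 support contains at least one masked-in pixel.
#'
#' @param patch A [gray_patch()] with bounding box at least 2x2.
#' @return A `haar_subbands` object: matrices `LL`, `LH`, `HL`, `HH`
#'   (dimensions `ceiling(H/2) x ceiling(W/2)`), logical `included`, and `n`
#'   the number of included coefficients.
#' @export
haar_decompose <- function(patch) {
  if (nrow(patch$pixels) < 2L || ncol(patch$pixels) < 2L) {
    stop("patch must be at least 2x2 for the Haar transform", call. = FALSE)
  }
  x <- patch$pixels
  fill <- as.integer(round(mean(x[patch$mask])))
  x[!patch$mask] <- fill
  x <- pad_even(x * 1.0)
  mk <- pad_even(patch$mask)
  ro <- seq(1L, nrow(x), by = 2L)
  co <- seq(1L, ncol(x), by = 2L)
  a <- x[ro, co, drop = FALSE]
  b <- x[ro, co + 1L, drop = FALSE]
  cc <- x[ro + 1L, co, drop = FALSE]
  d <- x[ro + 1L, co + 1L, drop = FALSE]
  included <- mk[ro, co, drop = FALSE] | mk[ro, co + 1L, drop = FALSE] |
    mk[ro + 1L, co, drop = FALSE] | mk[ro + 1L, co + 1L, drop = FALSE]
  structure(
    list(LL = (a + b + cc + d) / 2,
         LH = (a - b + cc - d) / 2,
         HL = (a + b - cc - d) / 2,
         HH = (a - b - cc + d) / 2,
         included = included, n = sum(included), scale = 1L,
         n_roi_pixels = sum(patch$mask)),
    class = "haar_subbands"
  )
}

#' @export
print.haar_subbands <- function(x, ...) {
  cat("<haar_subbands> level-1, ", nrow(x$LL), "x", ncol(x$LL),
      " coefficients per band (", x$n, " included)\n", sep = "")
  invisible(x)
}

#' Detail-subband energies EnLH, EnHL, EnHH
#'
#' The energy of a subband is the mean squared coefficient magnitude over
#' included coefficients, `E = sum(d^2) / n`. Constant patches have zero
#' detail energy; adding a constant to all intensities leaves the energies
#' unchanged, and scaling intensities by `c` scales them by `c^2`.
#'
#' @param sb A `haar_subbands` object from [haar_decompose()].
#' @param denominator See [wavelet_config()].
#' @return Named numeric vector `c(EnLH, EnHL, EnHH)`.
#' @export
subband_energies <- function(sb,
                             denominator = c("coefficients", "pixels")) {
  denominator <- match.arg(denominator)
  n <- if (denominator == "coefficients") sb$n else sb$n_roi_pixels
  if (n < 1L) stop("no included coefficients in subband", call. = FALSE)
  en <- function(band) sum(band[sb$included]^2) / n
  c(EnLH = en(sb$LH), EnHL = en(sb$HL), EnHH = en(sb$HH))
}
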