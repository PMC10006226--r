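#' GLCM computation settings
#'
#' @param distance Pixel displacement `d` (default 1: adjacent pixels).
#' @param angles Offset directions in degrees; subset of `{0, 45, 90, 135}`.
#'   With the default four directions and `average = TRUE`, each feature is
#'   the arithmetic mean over the four per-angle matrices, which makes the
#'   feature vector robust to in-plane rotation.
#' @param average If `TRUE` (default), [texture_features()] averages feature
#'   values over angles; per-angle values remain available via
#'   [compute_glcm()] + [glcm_features()].
#' @param k,n Exponents of the generalized contrast
#'   `CON = sum (i-j)^k p(i,j)^n`; the defaults `k = 2, n = 1` give the
#'   standard Haralick contrast.
#' @param symmetric If `TRUE` (default) each pixel pair is counted in both
#'   orders, making the matrix symmetric.
#' @return A list of class `glcm_config`.
#' @export
glcm_config <- function(distance = 1L, angles = c(0, 45, 90, 135),
                        average = TRUE, k = 2, n = 1, symmetric = TRUE) {
  distance <- as.integer(distance)
  if (distance < 1L) stop("distance must be >= 1", call. = FALSE)
  if (!all(angles %in% c(0, 45, 90, 135))) {
    stop("angles must be a subset of {0, 45, 90, 135} degrees", call. = FALSE)
  }
  if (k < 1 || n < 1) stop("contrast exponents k, n must be >= 1",
                           call. = FALSE)
  structure(list(distance = distance, angles = angles, average = average,
                 k = k, n = n, symmetric = symmetric),
            class = "glcm_config")
}

# (dy, dx) displacement for an angle, with rows growing downward: 0 deg is
# rightward, 45 deg up-right, 90 deg up, 135 deg up-left.
offset_for_angle <- function(angle, d) {
  switch(as.character(angle),
         "0"   = c(0L, d),
         "45"  = c(-d, d),
         "90"  = c(-d, 0L),
         "135" = c(-d, -d),
         stop("unsupported angle: ", angle, call. = FALSE))
}

#' Gray-level co-occurrence matrix over a masked ROI
#'
#' Counts ordered pairs of gray levels `(i, j)` at pixel positions separated
#' by the displacement of each requested angle. Only pairs with BOTH
#' endpoints inside the mask contribute, so cleared background never leaks
#' into the nuclear texture. Counts are normalized to probabilities
#' `p(i, j)` summing to 1.
#'
#' @param patch A quantized [gray_patch()] (`levels` = G).
#' @param config A [glcm_config()].
#' @param angle Optional single angle; if omitted, one matrix per configured
#'   angle is returned as a named list.
#' @return A `glcm` object (fields `p`, `levels`, `offset`, `angle`,
#'   `symmetric`, `pair_count`), or a named list of them.
#' @export
compute_glcm <- function(patch, config = glcm_config(), angle = NULL) {
  if (is.null(angle)) {
    out <- lapply(config$angles, function(a) compute_glcm(patch, config, a))
    names(out) <- paste0("deg", config$angles)
    return(out)
  }
  G <- patch$levels
  off <- offset_for_angle(angle, config$distance)
  dy <- off[1]; dx <- off[2]
  nr <- nrow(patch$pixels); nc <- ncol(patch$pixels)
  r1 <- max(1L, 1L - dy):min(nr, nr - dy)
  c1 <- max(1L, 1L - dx):min(nc, nc - dx)
  if (length(r1) < 1L || length(c1) < 1L) {
    stop("no valid pixel pairs for offset (dy=", dy, ", dx=", dx, ")",
         call. = FALSE)
  }
  a <- patch$pixels[r1, c1, drop = FALSE]
  b <- patch$pixels[r1 + dy, c1 + dx, drop = FALSE]
  ok <- patch$mask[r1, c1, drop = FALSE] &
    patch$mask[r1 + dy, c1 + dx, drop = FALSE]
  if (!any(ok)) {
    stop("no valid pixel pairs for offset (dy=", dy, ", dx=", dx,
         "): mask admits none", call. = FALSE)
  }
  counts <- tabulate(a[ok] * G + b[ok] + 1L, nbins = G * G)
  counts <- matrix(counts, nrow = G, ncol = G, byrow = TRUE)
  if (config$symmetric) counts <- counts + t(counts)
  structure(
    list(p = counts / sum(counts), levels = G, offset = c(dy = dy, dx = dx),
         angle = angle, distance = config$distance,
         symmetric = config$symmetric, pair_count = sum(counts)),
    class = "glcm"
  )
}

#' @export
print.glcm <- function(x, ...) {
  cat("<glcm> ", x$levels, " levels, d=", x$distance, ", angle=", x$angle,
      " deg, ", x$pair_count, " pairs",
      if (x$symmetric) " (symmetric)", "\n", sep = "")
  invisible(x)
}

#' Marginal distributions of a GLCM
#'
#' Row/column marginals `p_x`, `p_y` with their means and standard
#' deviations (used by the correlation feature), and the gray-level sum
#' distribution `p_{x+y}(s)`, `s = 0 .. 2(G-1)` (used by sum average and
#' sum variance).
#'
#' @param m A `glcm` object.
#' @return List with `p_x`, `p_y`, `mu_x`, `mu_y`, `sigma_x`, `sigma_y`,
#'   `p_sum` and the sum support `s`.
#' @export
glcm_marginals <- function(m) {
  G <- m$levels
  lev <- 0:(G - 1)
  p_x <- rowSums(m$p)
  p_y <- colSums(m$p)
  mu_x <- sum(lev * p_x)
  mu_y <- sum(lev * p_y)
  sigma_x <- sqrt(sum((lev - mu_x)^2 * p_x))
  sigma_y <- sqrt(sum((lev - mu_y)^2 * p_y))
  smat <- outer(lev, lev, `+`)
  p_sum <- as.vector(rowsum(as.vector(m$p), as.vector(smat)))
  list(p_x = p_x, p_y = p_y, mu_x = mu_x, mu_y = mu_y,
       sigma_x = sigma_x, sigma_y = sigma_y,
       p_sum = p_sum, s = 0:(2 * G - 2))
}

#' The six GLCM texture features of one co-occurrence matrix
#'
#' * `ASM` (angular second moment) `= sum p(i,j)^2` — textural uniformity,
#'   1 for a single-valued texture.
#' * `IDM` (inverse difference moment) `= sum p(i,j) / (1 + (i-j)^2)` —
#'   local homogeneity.
#' * `CON` (contrast) `= sum (i-j)^k p(i,j)^n` — local intensity variation.
#' * `COR` (correlation) `= (sum ij p(i,j) - mu_x mu_y) / (sigma_x sigma_y)`
#'   — gray-level linear dependency; `NA` when a marginal SD is zero
#'   (constant ROI), flagged rather than raised.
#' * `SA` (sum average) `= sum s p_{x+y}(s)` — mean of the gray-level sum
#'   distribution.
#' * `SVAR` (sum variance) `= sum (s - SA)^2 p_{x+y}(s)` — dispersion of the
#'   sum distribution around SA.
#'
#' @param m A `glcm` object (normalized).
#' @param config A [glcm_config()] supplying the contrast exponents.
#' @return Named numeric vector `c(ASM, IDM, CON, COR, SA, SVAR)`.
#' @export
glcm_features <- function(m, config = glcm_config()) {
  G <- m$levels
  lev <- 0:(G - 1)
  p <- m$p
  dmat <- outer(lev, lev, `-`)
  asm <- sum(p^2)
  idm <- sum(p / (1 + dmat^2))
  pn <- if (config$n == 1) p else p^config$n
  con <- sum(dmat^config$k * pn)
  mg <- glcm_marginals(m)
  cor <- if (mg$sigma_x * mg$sigma_y == 0) {
    NA_real_
  } else {
    (sum(outer(lev, lev) * p) - mg$mu_x * mg$mu_y) / (mg$sigma_x * mg$sigma_y)
  }
  sa <- sum(mg$s * mg$p_sum)
  svar <- sum((mg$s - sa)^2 * mg$p_sum)
  c(ASM = asm, IDM = idm, CON = con, COR = cor, SA = sa, SVAR = svar)
}

#' GLCM feature vector of a patch (averaged over angles)
#'
#' Computes one co-occurrence matrix per configured angle and, with
#' `config$average = TRUE`, returns the arithmetic mean of each feature over
#' the angles (an undefined COR at any angle makes the averaged COR `NA`).
#'
#' @param patch A quantized [gray_patch()].
#' @param config A [glcm_config()].
#' @return Named numeric vector of the six features, or a matrix with one
#'   row per angle when `config$average = FALSE`.
#' @export
glcm_feature_vector <- function(patch, config = glcm_config()) {
  mats <- compute_glcm(patch, config)
  per_angle <- t(vapply(mats, glcm_features, numeric(6), config = config))
  if (!config$average) {
    return(per_angle)
  }
  colMeans(per_angle)
}
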