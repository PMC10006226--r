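# Independent brute-force oracles and fixture builders. These deliberately
# use plain double loops and the literal feature formulas so they share no
# code with the vectorized implementation they check.

brute_glcm <- function(pixels, mask, G, dy, dx, symmetric = TRUE) {
  counts <- matrix(0, G, G)
  nr <- nrow(pixels); nc <- ncol(pixels)
  for (r in seq_len(nr)) for (cl in seq_len(nc)) {
    r2 <- r + dy; c2 <- cl + dx
    if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
        mask[r, cl] && mask[r2, c2]) {
      i <- pixels[r, cl] + 1L; j <- pixels[r2, c2] + 1L
      counts[i, j] <- counts[i, j] + 1
      if (symmetric) counts[j, i] <- counts[j, i] + 1
    }
  }
  counts / sum(counts)
}

brute_glcm_features <- function(p, k = 2, n = 1) {
  G <- nrow(p)
  asm <- 0; idm <- 0; con <- 0; sij <- 0
  for (i in 0:(G - 1)) for (j in 0:(G - 1)) {
    pij <- p[i + 1, j + 1]
    asm <- asm + pij^2
    idm <- idm + pij / (1 + (i - j)^2)
    con <- con + (i - j)^k * pij^n
    sij <- sij + i * j * pij
  }
  px <- rowSums(p); py <- colSums(p)
  mux <- sum((0:(G - 1)) * px); muy <- sum((0:(G - 1)) * py)
  sx <- sqrt(sum(((0:(G - 1)) - mux)^2 * px))
  sy <- sqrt(sum(((0:(G - 1)) - muy)^2 * py))
  cor <- if (sx * sy == 0) NA_real_ else (sij - mux * muy) / (sx * sy)
  psum <- numeric(2 * G - 1)
  for (i in 0:(G - 1)) for (j in 0:(G - 1)) {
    psum[i + j + 1] <- psum[i + j + 1] + p[i + 1, j + 1]
  }
  sa <- sum((0:(2 * G - 2)) * psum)
  svar <- sum(((0:(2 * G - 2)) - sa)^2 * psum)
  c(ASM = asm, IDM = idm, CON = con, COR = cor, SA = sa, SVAR = svar)
}

# random patch with an elliptical mask, already quantized to G levels
random_masked_patch <- function(size = 16L, G = 8L) {
  px <- matrix(sample(0:(G - 1L), size * size, replace = TRUE), size, size)
  ctr <- (size + 1) / 2
  a <- stats::runif(1, size / 4, size / 2.2)
  b <- stats::runif(1, size / 4, size / 2.2)
  dx <- outer(rep(1, size), seq_len(size) - ctr)
  dy <- outer(seq_len(size) - ctr, rep(1, size))
  mask <- (dx / a)^2 + (dy / b)^2 <= 1
  gray_patch(px, mask, levels = G)
}

# smooth base texture used for the noise-response checks: a blurred random
# field on a full square mask, on the 8-bit scale
smooth_base_patch <- function(size = 48L, amplitude = 20, sigma = 6) {
  f <- matrix(stats::rnorm(size * size), size, size)
  kr <- ceiling(3 * sigma)
  k <- stats::dnorm(-kr:kr, sd = sigma); k <- k / sum(k)
  f <- apply(f, 2, function(col) {
    stats::filter(c(rep(col[1], kr), col, rep(col[length(col)], kr)), k,
                  sides = 2)[(kr + 1):(kr + size)]
  })
  f <- t(apply(f, 1, function(row) {
    stats::filter(c(rep(row[1], kr), row, rep(row[length(row)], kr)), k,
                  sides = 2)[(kr + 1):(kr + size)]
  }))
  f <- (f - mean(f)) / stats::sd(f)
  round(pmin(pmax(128 + amplitude * f, 0), 255))
}

write_tiny_roi <- function(dir, pixels, mask, roi_id = "roi_1", group = 0L,
                           animal_id = "A1") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  img_path <- file.path(dir, paste0(roi_id, ".png"))
  msk_path <- file.path(dir, paste0(roi_id, "_mask.png"))
  write_image_png(pixels, img_path)
  write_image_png(mask, msk_path)
  data.frame(roi_id = roi_id, image_path = img_path, mask_path = msk_path,
             group = group, animal_id = animal_id, stringsAsFactors = FALSE)
}
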