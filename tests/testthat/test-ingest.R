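test_that("grayscale conversion uses BT.601 weights with fixed points", {
  rgb <- array(0L, c(2, 2, 3))
  rgb[1, 1, ] <- c(255L, 255L, 255L)
  rgb[1, 2, ] <- c(0L, 0L, 0L)
  rgb[2, 1, ] <- c(100L, 100L, 100L)
  rgb[2, 2, ] <- c(255L, 0L, 0L)
  g <- rgb_to_gray(rgb)
  expect_identical(g[1, 1], 255L)
  expect_identical(g[1, 2], 0L)
  expect_identical(g[2, 1], 100L)
  expect_identical(g[2, 2], as.integer(round(0.299 * 255)))
  # already-gray input passes through untouched
  m <- matrix(5L, 3, 3)
  expect_identical(rgb_to_gray(m), m)
  expect_error(rgb_to_gray(array(0L, c(2, 2, 4))), "3-channel")
})

test_that("quantization strategies match their closed-form definitions", {
  const <- gray_patch(matrix(77L, 5, 5))
  expect_true(all(quantize_gray(const, 64, "minmax")$pixels == 0L))
  expect_true(all(quantize_gray(const, 64, "sigma3")$pixels == 0L))

  two <- gray_patch(matrix(c(10L, 250L), 2, 2))
  q <- quantize_gray(two, 64, "minmax")
  expect_setequal(unique(as.vector(q$pixels)), c(0L, 63L))
  expect_identical(q$levels, 64L)

  v <- matrix(0:255, 16, 16)
  storage.mode(v) <- "integer"
  qb <- quantize_gray(gray_patch(v), 64, "bitshift")
  expect_identical(qb$pixels, v %/% 4L)

  expect_error(quantize_gray(const, 63), "power of two")
})

test_that("quantization is monotone and stays within [0, G-1]", {
  set.seed(11)
  for (strategy in c("minmax", "bitshift", "sigma3")) {
    for (G in c(8L, 32L, 256L)) {
      px <- matrix(sample(0:255, 100, replace = TRUE), 10, 10)
      storage.mode(px) <- "integer"
      q <- quantize_gray(gray_patch(px), G, strategy)
      expect_true(all(q$pixels >= 0L & q$pixels <= G - 1L))
      ord <- order(as.vector(px))
      expect_true(all(diff(as.vector(q$pixels)[ord]) >= 0),
                  info = paste(strategy, G))
    }
  }
})

test_that("ROI loading crops to the mask bounding box", {
  set.seed(21)
  px <- matrix(sample(0:255, 100, replace = TRUE), 10, 10)
  storage.mode(px) <- "integer"
  dir <- withr::local_tempdir()

  full <- write_tiny_roi(dir, px, matrix(TRUE, 10, 10), "full")
  p <- load_roi(full[1, ])
  expect_identical(p$pixels, px)
  expect_identical(p$origin, c(0L, 0L))

  mask <- matrix(FALSE, 10, 10)
  mask[3:6, 4:8] <- TRUE
  sub <- write_tiny_roi(dir, px, mask, "sub")
  p <- load_roi(sub[1, ])
  expect_identical(dim(p$pixels), c(4L, 5L))
  expect_identical(p$origin, c(2L, 3L))

  # masked-in pixel multiset is preserved by cropping
  rmask <- matrix(stats::runif(100) < 0.4, 10, 10)
  rmask[5, 5] <- TRUE
  rnd <- write_tiny_roi(dir, px, rmask, "rnd")
  p <- load_roi(rnd[1, ], min_pixels = 1L)
  expect_identical(sort(p$pixels[p$mask]), sort(px[rmask]))
})

test_that("mask PNG round-trip is bit-exact and bad inputs error", {
  set.seed(31)
  dir <- withr::local_tempdir()
  mask <- matrix(stats::runif(64) < 0.5, 8, 8)
  path <- file.path(dir, "m.png")
  write_image_png(mask, path)
  expect_identical(read_image(path) != 0L, mask)

  px <- matrix(1L, 8, 8)
  rec <- write_tiny_roi(dir, px, matrix(FALSE, 8, 8), "empty")
  expect_error(load_roi(rec[1, ]), "empty mask")
  rec2 <- write_tiny_roi(dir, px, matrix(TRUE, 4, 4), "mismatch")
  expect_error(load_roi(rec2[1, ]), "dimensions")
})

test_that("manifest reading validates schema and resolves relative paths", {
  dir <- withr::local_tempdir()
  man <- data.frame(roi_id = "r1", image_path = "images/r1.png",
                    mask_path = "masks/r1.png", group = 1L,
                    animal_id = "A1")
  path <- file.path(dir, "manifest.csv")
  write.csv(man, path, row.names = FALSE)
  m <- read_manifest(path)
  expect_identical(m$image_path, file.path(dir, "images/r1.png"))

  bad <- man; bad$group <- 2L
  write.csv(bad, path, row.names = FALSE)
  expect_error(read_manifest(path), "0 .*1|group")
  write.csv(man[, -1], path, row.names = FALSE)
  expect_error(read_manifest(path), "roi_id")
})
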