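test_that("co-occurrence probabilities match hand-counted tiny patches", {
  const <- gray_patch(matrix(0L, 2, 2), levels = 2)
  m <- compute_glcm(const, glcm_config(angles = 0), angle = 0)
  expect_equal(m$p[1, 1], 1)
  expect_equal(sum(m$p), 1)

  stripes <- gray_patch(matrix(c(0L, 0L, 1L, 1L), 2, 2), levels = 2)
  m <- compute_glcm(stripes, glcm_config(angles = 0), angle = 0)
  expect_equal(m$p[1, 2], 0.5)
  expect_equal(m$p[2, 1], 0.5)
  expect_equal(m$p[1, 1] + m$p[2, 2], 0)
})

test_that("vectorized GLCM equals the brute-force pair enumerator", {
  set.seed(101)
  cfg <- glcm_config()
  offsets <- list(`0` = c(0, 1), `45` = c(-1, 1), `90` = c(-1, 0),
                  `135` = c(-1, -1))
  for (rep in 1:10) {
    patch <- random_masked_patch(16L, 8L)
    mats <- compute_glcm(patch, cfg)
    for (ang in names(offsets)) {
      oracle <- brute_glcm(patch$pixels, patch$mask, 8L,
                           offsets[[ang]][1], offsets[[ang]][2])
      expect_lt(max(abs(mats[[paste0("deg", ang)]]$p - oracle)), 1e-12)
      expect_equal(glcm_features(mats[[paste0("deg", ang)]], cfg),
                   brute_glcm_features(oracle), tolerance = 1e-12)
    }
  }
})

test_that("feature values of canonical matrices match closed forms", {
  # constant patch via bitshift keeps its absolute level: p(25,25) = 1
  const <- gray_patch(matrix(100L, 4, 4))
  q <- quantize_gray(const, 64, "bitshift")
  m <- compute_glcm(q, glcm_config(angles = 0), angle = 0)
  f <- glcm_features(m)
  expect_equal(f[["ASM"]], 1)
  expect_equal(f[["IDM"]], 1)
  expect_equal(f[["CON"]], 0)
  expect_true(is.na(f[["COR"]]))
  expect_equal(f[["SA"]], 2 * 25)
  expect_equal(f[["SVAR"]], 0)

  # 4x4 checkerboard of levels {0,1}, horizontal offset
  chk <- gray_patch(outer(1:4, 1:4, function(r, c) (r + c) %% 2L),
                    levels = 2)
  m <- compute_glcm(chk, glcm_config(angles = 0), angle = 0)
  f <- glcm_features(m)
  expect_equal(f[["ASM"]], 0.5)
  expect_equal(f[["IDM"]], 0.5)
  expect_equal(f[["CON"]], 1)
  expect_equal(f[["COR"]], -1)
  expect_equal(f[["SA"]], 1)
  expect_equal(f[["SVAR"]], 0)
})

test_that("GLCM invariants hold on random masked patches", {
  set.seed(202)
  cfg <- glcm_config()
  for (rep in 1:20) {
    patch <- random_masked_patch(12L, 8L)
    mats <- compute_glcm(patch, cfg)
    for (m in mats) {
      expect_equal(sum(m$p), 1, tolerance = 1e-12)
      expect_true(all(m$p >= 0))
      expect_identical(m$p, t(m$p))
      f <- glcm_features(m, cfg)
      expect_true(f[["ASM"]] > 0 && f[["ASM"]] <= 1)
      expect_true(f[["IDM"]] > 0 && f[["IDM"]] <= 1)
      expect_gte(f[["CON"]], 0)
      expect_gte(f[["SVAR"]], -1e-12)
      expect_true(f[["SA"]] >= 0 && f[["SA"]] <= 2 * (m$levels - 1))
      if (!is.na(f[["COR"]])) {
        expect_true(f[["COR"]] >= -1 - 1e-12 && f[["COR"]] <= 1 + 1e-12)
      }
      # features are invariant to transposing a symmetric matrix
      mt <- m; mt$p <- t(m$p)
      expect_equal(glcm_features(mt, cfg), f)
    }
  }
})

test_that("angle averaging is the mean of per-angle features", {
  set.seed(303)
  patch <- random_masked_patch(16L, 8L)
  cfg <- glcm_config()
  per_angle <- glcm_feature_vector(patch, glcm_config(average = FALSE))
  expect_identical(dim(per_angle), c(4L, 6L))
  expect_equal(glcm_feature_vector(patch, cfg), colMeans(per_angle))
})

test_that("offsets with no valid pair raise an error naming the offset", {
  lonely <- matrix(FALSE, 3, 3); lonely[2, 2] <- TRUE
  patch <- gray_patch(matrix(0L, 3, 3), lonely, levels = 2)
  expect_error(compute_glcm(patch, glcm_config(angles = 0), angle = 0),
               "dy=0, dx=1")
})
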