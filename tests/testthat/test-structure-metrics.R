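test_that("short-range order ratio: symmetry, linearity, fixture truth", {
  expect_equal(short_range_order(ftir_fixture(1)), 1, tolerance = 1e-6)
  expect_equal(short_range_order(ftir_fixture(1.10)), 1.10,
               tolerance = 1e-4)
  # prescribed 0.72 ratio on a sloped baseline
  sp <- ftir_fixture(0.72, baseline = c(0.001, 0.5))
  expect_equal(short_range_order(sp), 0.72, tolerance = 1e-3)
  # positive-scale invariance
  sp2 <- spectrum_xy(sp$x, 3 * sp$y)
  expect_equal(short_range_order(sp2), short_range_order(sp),
               tolerance = 1e-9)
  narrow <- gen_spectrum(data.frame(center = 1000, height = 1, width = 5),
                         seq(900, 1100, by = 1))
  expect_error(short_range_order(narrow), "800-1200")
})

test_that("relative crystallinity: halo-only, known peak fraction, scale
           invariance", {
  fx <- xrd_fixture(23.7)
  expect_lt(relative_crystallinity(fx$halo_only), 2)
  rc <- relative_crystallinity(fx$spectrum)
  expect_equal(rc, 23.7, tolerance = 1 / 23.7) # within 1 percentage point
  doubled <- spectrum_xy(fx$spectrum$x, 2 * fx$spectrum$y)
  expect_equal(relative_crystallinity(doubled), rc, tolerance = 1e-9)
})

test_that("Rq: constant, checkerboard and generated maps", {
  expect_equal(rms_roughness(height_map(matrix(5, 32, 32))), 0)
  cb <- height_map(outer(1:32, 1:32, function(i, j) (-1)^(i + j)))
  expect_equal(rms_roughness(cb), 1)
  hm <- gen_height_map(height_map_spec(n_pixels = 64, target_rq = 8.01,
                                       corr_length = 60, seed = 3))
  expect_equal(rms_roughness(hm), 8.01, tolerance = 1e-12)
})

test_that("GLCM features: constant map, hand-enumerated checkerboard,
           normalization bounds", {
  const <- glcm_features(height_map(matrix(2, 32, 32)))
  expect_equal(const$energy, 1)
  expect_equal(const$contrast, 0)
  expect_equal(const$homogeneity, 1)
  expect_equal(const$entropy, 0)
  # 2-level checkerboard, single (0,1) offset: the two off-diagonal cells
  # each hold probability 1/2
  cb <- height_map(outer(1:32, 1:32, function(i, j) (i + j) %% 2))
  g <- glcm_features(cb, levels = 2, offsets = list(c(0L, 1L)))
  expect_equal(g$contrast, 1)
  expect_equal(g$energy, 0.5)
  expect_equal(g$entropy, log(2))
  expect_equal(g$homogeneity, 0.5)
  # generic map: energy and homogeneity bounded by 1
  hm <- gen_height_map(height_map_spec(n_pixels = 64, target_rq = 5,
                                       corr_length = 100, seed = 9))
  f <- glcm_features(hm)
  expect_lte(f$energy, 1)
  expect_lte(f$homogeneity, 1)
  expect_gte(f$contrast, 0)
  expect_gte(f$entropy, 0)
})

test_that("entropy is maximal for the uniform co-occurrence distribution", {
  # a map cycling through all levels row-wise approximates the uniform
  # pairing; its entropy must not exceed log(levels^2) and must beat the
  # checkerboard's
  cyc <- height_map(outer(1:32, 1:32, function(i, j) (i + j) %% 4))
  g4 <- glcm_features(cyc, levels = 4, offsets = list(c(0L, 1L)))
  cb <- glcm_features(
    height_map(outer(1:32, 1:32, function(i, j) (i + j) %% 2)),
    levels = 4, offsets = list(c(0L, 1L))
  )
  expect_lte(g4$entropy, log(16))
  expect_gt(g4$entropy, cb$entropy)
})

test_that("texture trend with increasing surface disorder", {
  cls <- c(240, 60, 24) # decreasing correlation length = rougher texture
  feats <- lapply(cls, function(cl) {
    glcm_features(gen_height_map(height_map_spec(
      n_pixels = 128, target_rq = 8, corr_length = cl, seed = 5
    )))
  })
  en <- vapply(feats, `[[`, numeric(1), "entropy")
  ct <- vapply(feats, `[[`, numeric(1), "contrast")
  eg <- vapply(feats, `[[`, numeric(1), "energy")
  hg <- vapply(feats, `[[`, numeric(1), "homogeneity")
  expect_true(all(diff(en) > 0))
  expect_true(all(diff(ct) > 0))
  expect_true(all(diff(eg) < 0))
  expect_true(all(diff(hg) < 0))
})

test_that("box dimension: planes are 2, flat maps flagged, offsets
           irrelevant", {
  plane <- height_map(outer(1:128, 1:128, function(i, j) 0.3 * i + 0.1 * j))
  expect_equal(box_fractal_dimension(plane)$dimension, 2,
               tolerance = 0.025)
  flat <- box_fractal_dimension(height_map(matrix(1, 64, 64)))
  expect_equal(flat$dimension, 2)
  expect_true(flat$flag_flat)
  shifted <- height_map(plane$heights + 100)
  expect_equal(box_fractal_dimension(shifted)$dimension,
               box_fractal_dimension(plane)$dimension)
})

test_that("box dimension tracks the Hurst exponent of fBm surfaces", {
  d_of <- function(h) {
    box_fractal_dimension(gen_fbm_surface(256, h, seed = 4))$dimension
  }
  d_rough <- d_of(0.2)
  d_mid <- d_of(0.5)
  d_smooth <- d_of(0.8)
  expect_gt(d_rough, d_mid)
  expect_gt(d_mid, d_smooth)
  expect_gt(d_smooth, 2)
  expect_lt(d_rough, 3)
})
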