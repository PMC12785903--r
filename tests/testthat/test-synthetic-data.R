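test_that("single-phase generator matches the first-order closed form", {
  tt <- times_uniform(20, 600)
  crv <- gen_digestion_curve(list(phase_spec(0.02, 60, 600)), tt)
  expect_equal(crv$C, 60 * (1 - exp(-0.02 * tt)))
  expect_equal(crv$C[1], 0)
  # asymptote
  far <- gen_digestion_curve(list(phase_spec(0.02, 60, 5000)),
                             c(0, 2500, 5000))
  expect_equal(far$C[3], 60, tolerance = 1e-8)
})

test_that("multi-phase curves are continuous, non-decreasing and bounded", {
  for (phases in list(ternary_phases(), paste_phases())) {
    crv <- gen_digestion_curve(phases, times_uniform(1))
    expect_true(all(diff(crv$C) >= 0))
    expect_true(all(crv$C >= 0 & crv$C <= 100))
    # value continuity at the breakpoint (the hydrolysis rate may change
    # discontinuously, the curve itself may not)
    t1 <- phases[[1]]$t_end
    eps <- 1e-7
    dense <- gen_digestion_curve(phases, c(0, t1 - eps, t1, t1 + eps))
    expect_lt(abs(dense$C[3] - dense$C[2]), 1e-5)
    expect_lt(abs(dense$C[4] - dense$C[3]), 1e-5)
  }
})

test_that("generator validates phases, times and noise", {
  expect_error(gen_digestion_curve(list(), times_uniform(5)), "empty")
  expect_error(phase_spec(0.02, 101, 100), "C_inf")
  expect_error(phase_spec(-1, 50, 100), "k")
  bad_order <- list(phase_spec(0.01, 50, 100), phase_spec(0.02, 60, 200))
  expect_error(gen_digestion_curve(bad_order, times_uniform(5, 200)),
               "decreasing")
  expect_error(
    gen_digestion_curve(list(phase_spec(0.02, 60, 100)), c(0, 50, 50)),
    "increasing"
  )
  expect_error(
    gen_digestion_curve(list(phase_spec(0.02, 60, 100)), c(0, 50, 200)),
    "exceeds"
  )
})

test_that("digestion noise is seeded, clipped and reproducible", {
  ph <- list(phase_spec(0.05, 90, 540))
  a <- gen_digestion_curve(ph, times_protocol(), noise_sd = 1.5, seed = 42)
  b <- gen_digestion_curve(ph, times_protocol(), noise_sd = 1.5, seed = 42)
  c2 <- gen_digestion_curve(ph, times_protocol(), noise_sd = 1.5, seed = 43)
  expect_identical(a$C, b$C)
  expect_false(identical(a$C, c2$C))
  expect_true(all(a$C >= 0 & a$C <= 100))
})

test_that("curve_to_glucose inverts the percent-hydrolyzed definition", {
  crv <- gen_digestion_curve(ternary_phases(), times_protocol())
  gs <- curve_to_glucose(crv, TS = 200, GF = 0)
  expect_equal(glucose_to_curve(gs)$C, crv$C)
  # C = 45 %, TS = 200 mg -> 100 mg glucose
  one <- curve_to_glucose(digestion_curve(c(0, 20), c(0, 45)), TS = 200)
  expect_equal(one$glucose[2], 100)
  # zero curve, GF = 0 -> zero glucose
  z <- curve_to_glucose(digestion_curve(c(0, 20), c(0, 0)), TS = 200)
  expect_equal(z$glucose, c(0, 0))
  # GF offsets round-trip too
  gf <- curve_to_glucose(crv, TS = 180, GF = 3)
  expect_equal(glucose_to_curve(gf)$C, crv$C)
})

test_that("lamellar scattering generator is seeded and periodic stacks peak
           at the long period", {
  q <- seq(0.02, 0.5, by = 0.002)
  sp <- stack_spec(5, 5, 0, 0, n_repeats = 24)
  a <- gen_lamellar_scattering(sp, q, n_realizations = 2, seed = 9)
  b <- gen_lamellar_scattering(sp, q, n_realizations = 2, seed = 9)
  expect_identical(a$curve$I, b$curve$I)
  expect_identical(a$cf$L, b$cf$L)
  expect_equal(a$cf$L[1], 1)
  # periodic stack: first local maximum of the oracle at d_c + d_a
  lam <- lamellar_params(a$cf)
  expect_equal(lam$d, 10, tolerance = 0.01)
  # equal-thickness stack: thinner layer = d / 2
  expect_equal(lam$thinner, 5, tolerance = 0.05)
})

test_that("lamellar generator rejects too-narrow q windows", {
  sp <- stack_spec(1.99, 1.98, 0, 0, n_repeats = 24)
  expect_error(
    gen_lamellar_scattering(sp, seq(0.01, 0.25, by = 0.002),
                            n_realizations = 1, seed = 1),
    "too narrow"
  )
})

test_that("spectrum generator: zero case, symmetry and Gaussian areas", {
  x <- seq(800, 1200, by = 1)
  z <- gen_spectrum(data.frame(center = numeric(0), height = numeric(0),
                               width = numeric(0)), x)
  expect_equal(z$y, rep(0, length(x)))
  # two equal Gaussians at the band positions give ratio 1
  expect_equal(short_range_order(ftir_fixture(1)), 1, tolerance = 1e-6)
  # closed-form Gaussian area h * w * sqrt(2 pi) recovered by trapezoid
  g <- gen_spectrum(data.frame(center = 1000, height = 2, width = 12),
                    x, baseline = c(0.01, 1))
  base <- 0.01 * x + 1
  area <- pracma::trapz(x, g$y - base)
  expect_equal(area, 2 * 12 * sqrt(2 * pi), tolerance = 0.01)
})

test_that("height-map generator hits target Rq exactly and is seeded", {
  sp <- height_map_spec(n_pixels = 64, target_rq = 8.01, corr_length = 60,
                        seed = 1)
  hm <- gen_height_map(sp)
  expect_equal(rms_roughness(hm), 8.01, tolerance = 1e-12)
  hm2 <- gen_height_map(height_map_spec(n_pixels = 64, target_rq = 8.01,
                                        corr_length = 60, seed = 2))
  expect_false(identical(hm$heights, hm2$heights))
  expect_equal(rms_roughness(hm2), 8.01, tolerance = 1e-12)
  # zero roughness -> constant zero map
  z <- gen_height_map(height_map_spec(n_pixels = 64, target_rq = 0,
                                      corr_length = 60, seed = 1))
  expect_true(all(z$heights == 0))
  expect_error(height_map_spec(target_rq = -1), "target_rq")
})

test_that("fBm surface has the prescribed small-lag scaling", {
  z <- gen_fbm_surface(256, hurst = 0.5, seed = 1)$heights
  v <- vapply(c(1, 2, 4, 8), function(l) {
    mean((z[, (1 + l):256] - z[, 1:(256 - l)])^2)
  }, numeric(1))
  # variogram ratios close to 2^(2H) = 2 per lag doubling
  ratios <- v[-1] / v[-4]
  expect_true(all(abs(ratios - 2) < 0.45))
})
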