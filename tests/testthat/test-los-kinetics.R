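test_that("classical first-order fit recovers exact-model parameters", {
  crv <- gen_digestion_curve(list(phase_spec(0.02, 60, 600)),
                             times_uniform(20, 600))
  fit <- fit_first_order(crv)
  expect_equal(fit$C_inf, 60, tolerance = 1e-3)
  expect_equal(fit$k, 0.02, tolerance = 1e-3)
  expect_gt(fit$r_squared, 0.99999)
  # WMA-paste phase-II parameters on the protocol grid
  crv2 <- gen_digestion_curve(list(phase_spec(3.20e-2, 90.13, 540)),
                              times_protocol())
  fit2 <- fit_first_order(crv2)
  expect_equal(fit2$C_inf, 90.13, tolerance = 0.01 * 90.13)
  expect_equal(fit2$k, 3.20e-2, tolerance = 0.01 * 3.20e-2)
  expect_error(fit_first_order(digestion_curve(0:5, rep(0, 6))),
               "increments")
})

test_that("los_transform matches the printed difference quotient", {
  pts <- los_transform(digestion_curve(c(0, 1, 2), c(0, 10, 15)))
  expect_equal(pts$x, c(0.5, 1.5))
  expect_equal(pts$y, c(log(10), log(5)))
  expect_identical(attr(pts, "dropped_points"), 0L)
  # flat increment dropped and counted
  pts2 <- los_transform(digestion_curve(c(0, 1, 2, 3), c(0, 10, 10, 15)))
  expect_identical(attr(pts2, "dropped_points"), 1L)
  expect_equal(nrow(pts2), 2L)
  expect_error(los_transform(digestion_curve(c(0, 1, 2), c(5, 5, 5))),
               "usable")
})

test_that("uniform-grid LOS points are collinear with slope -k and the
           intercept carries the sinh correction", {
  k <- 0.0243
  C_inf <- 60.21
  delta <- 5
  crv <- gen_digestion_curve(list(phase_spec(k, C_inf, 540)),
                             times_uniform(delta))
  pts <- los_transform(crv)
  fit <- fit_phase(pts, times = crv$times)
  expect_equal(fit$k, k, tolerance = 1e-9)
  expect_gt(fit$r_squared, 1 - 1e-12)
  # recovered C_inf biased by exactly sinh(k delta / 2) / (k delta / 2)
  bias <- sinh(k * delta / 2) / (k * delta / 2)
  expect_equal(fit$C_inf, C_inf * bias, tolerance = 1e-8)
})

test_that("fit_phase inverts the LOS line and flags degenerate cases", {
  x <- seq(10, 100, by = 10)
  y <- -0.02 * x + log(60 * 0.02)
  pts <- structure(data.frame(x = x, y = y, from_index = seq_along(x)),
                   class = c("los_points", "data.frame"))
  fit <- fit_phase(pts)
  expect_equal(fit$k, 0.02)
  expect_equal(fit$C_inf, 60)
  expect_false(fit$flag_C_inf_above_100)
  up <- pts
  up$y <- 0.01 * x
  expect_error(fit_phase(up), "slope")
  expect_error(fit_phase(pts[1:3, ]), "4")
})

test_that("segment_phases: parsimony on one line, exact recovery of a
           junction, monotone-k constraint", {
  x <- seq_len(20)
  one <- structure(data.frame(x = x, y = -0.05 * x + 1,
                              from_index = x),
                   class = c("los_points", "data.frame"))
  expect_identical(segment_phases(one), integer(0))
  # two exact lines crossing between samples at x = 10.5
  # (k drops from 0.08 to 0.02)
  y2 <- ifelse(x <= 10, -0.08 * x + 1, -0.02 * x + 1 - 0.06 * 10.5)
  two <- structure(data.frame(x = x, y = y2, from_index = x),
                   class = c("los_points", "data.frame"))
  expect_identical(segment_phases(two), 10L)
  # k increasing (slope decreasing) is inadmissible as a 2-phase model
  y3 <- ifelse(x <= 10, -0.02 * x + 1, -0.08 * x + 1 + 0.06 * 10)
  three <- structure(data.frame(x = x, y = y3, from_index = x),
                     class = c("los_points", "data.frame"))
  fits_one <- segment_phases(three)
  expect_identical(fits_one, integer(0)) # falls back to a single phase
})

test_that("full pipeline recovers the two-phase ternary parameters on a
           uniform grid", {
  crv <- gen_digestion_curve(ternary_phases(), times_uniform(5))
  res <- analyze_digestion(crv, reference = crv)
  expect_length(res$phases, 2L)
  expect_equal(res$breakpoints, 200)
  expect_equal(res$phases[[1]]$k, 2.43e-2, tolerance = 1e-10)
  expect_equal(res$phases[[2]]$k, 1.44e-2, tolerance = 1e-10)
  expect_equal(res$phases[[1]]$C_inf, 60.21, tolerance = 0.01 * 60.21)
  expect_equal(res$phases[[2]]$C_inf, 61.06, tolerance = 0.01 * 61.06)
  expect_equal(res$HI, 100)
  expect_equal(res$EGI, 39.71 + 54.9)
  # classical k lies between k2 and k1
  expect_gt(res$classical$k, 1.44e-2)
  expect_lt(res$classical$k, 2.43e-2)
  # phase k values strictly decreasing
  ks <- vapply(res$phases, `[[`, numeric(1), "k")
  expect_true(all(diff(ks) < 0))
})

test_that("single-phase curves give agreeing classical and LOS rates", {
  crv <- gen_digestion_curve(list(phase_spec(0.03, 80, 540)),
                             times_uniform(5))
  res <- analyze_digestion(crv)
  expect_length(res$phases, 1L)
  expect_equal(res$phases[[1]]$k, res$classical$k,
               tolerance = 1e-3 * res$classical$k)
  expect_null(res$HI)
})

test_that("curves with many non-positive increments warn and count drops", {
  set.seed(8)
  ph <- list(phase_spec(0.25, 55, 540))
  crv <- gen_digestion_curve(ph, times_uniform(10), noise_sd = 1.2,
                             seed = 77)
  # saturation + noise produces many non-increasing steps (and may also
  # trigger the AUC-reliability diagnostic)
  w <- capture_warnings(res <- analyze_digestion(crv))
  expect_match(w, "dropped", all = FALSE)
  expect_gt(res$dropped_points, 0.3 * (length(crv$times) - 1))
})

test_that("AUC formula, HI scale and EGI line are exact", {
  expect_equal(auc_first_order(50, 0.01, 0, 100),
               5000 - 5000 * (1 - exp(-1)))
  expect_equal(auc_first_order(50, 0.01, 40, 40), 0)
  # instantaneous-saturation limit
  expect_equal(auc_first_order(50, 1e6, 0, 100), 50 * 100,
               tolerance = 1e-3)
  # monotone in C_inf and interval width
  expect_gt(auc_first_order(60, 0.01, 0, 100),
            auc_first_order(50, 0.01, 0, 100))
  expect_gt(auc_first_order(50, 0.01, 0, 120),
            auc_first_order(50, 0.01, 0, 100))
  expect_error(auc_first_order(50, 0, 0, 10), "k")
  expect_equal(hydrolysis_index(70, 70), 100)
  expect_equal(hydrolysis_index(0, 70), 0)
  expect_equal(hydrolysis_index(0.7183, 1), 71.83)
  expect_error(hydrolysis_index(1, 0), "reference")
  expect_equal(egi(0), 39.71)
  expect_equal(egi(105.30), 97.52, tolerance = 0.01)
  expect_equal(egi(83.99), 85.82, tolerance = 0.01)
  # affine and strictly increasing
  his <- c(0, 20, 50, 90)
  expect_true(all(diff(egi(his)) > 0))
  expect_equal(diff(egi(his)) / diff(his), rep(0.549, 3))
})
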