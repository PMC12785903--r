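#' Specify a synthetic AFM height map
#'
#' Correlated Gaussian random height field with a prescribed RMS roughness:
#' white noise is low-pass filtered at the lateral correlation length,
#' mean-subtracted, and rescaled so the sample RMS equals `target_rq`
#' exactly.
#'
#' @param n_pixels Side length in pixels, >= 16.
#' @param pixel_size Lateral sampling, nm/pixel, > 0.
#' @param target_rq Prescribed RMS roughness, nm, >= 0.
#' @param corr_length Lateral correlation length, nm, > 0.
#' @param seed Integer seed.
#' @return An object of class `height_map_spec`.
#' @export
height_map_spec <- function(n_pixels = 128L, pixel_size = 2000 / 128,
                            target_rq = 8.01, corr_length = 60,
                            seed = 1L) {
  stopifnot(n_pixels >= 16, pixel_size > 0, corr_length > 0)
  if (target_rq < 0) stop("`target_rq` must be >= 0", call. = FALSE)
  structure(
    list(n_pixels = as.integer(n_pixels), pixel_size = pixel_size,
         target_rq = target_rq, corr_length = corr_length,
         seed = as.integer(seed)),
    class = "height_map_spec"
  )
}

#' Construct a height map
#'
#' A square grid of surface heights (nm) with its lateral sampling, the
#' container for all surface texture metrics. The default scan emulates a
#' 2 um x 2 um AFM field.
#'
#' @param heights Square numeric matrix of heights, nm, finite.
#' @param pixel_size Lateral sampling, nm/pixel.
#' @return An object of class `height_map`.
#' @export
height_map <- function(heights, pixel_size = 2000 / nrow(heights)) {
  heights <- as.matrix(heights)
  if (nrow(heights) != ncol(heights)) {
    stop("`heights` must be square", call. = FALSE)
  }
  if (any(!is.finite(heights))) {
    stop("`heights` must be finite", call. = FALSE)
  }
  structure(list(heights = heights, pixel_size = pixel_size,
                 scan_size = pixel_size * nrow(heights)),
            class = "height_map")
}

#' @export
print.height_map <- function(x, ...) {
  cat(sprintf("<height_map> %d x %d px, %.1f nm/px (%.0f nm scan)\n",
              nrow(x$heights), ncol(x$heights), x$pixel_size, x$scan_size))
  invisible(x)
}

# isotropic Gaussian low-pass via FFT, sigma in pixels
fft_lowpass <- function(z, sigma_px) {
  n <- nrow(z)
  f <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / n
  fx <- matrix(f, n, n)
  fy <- t(fx)
  H <- exp(-2 * pi^2 * sigma_px^2 * (fx^2 + fy^2))
  Re(stats::fft(stats::fft(z) * H, inverse = TRUE)) / n^2
}

#' Generate a correlated random height map
#'
#' Seeded Gaussian white noise is low-pass filtered (Gaussian kernel with
#' standard deviation `corr_length` in real units), mean-subtracted, and
#' rescaled so the sample RMS roughness equals `target_rq` exactly (to
#' machine precision). `target_rq = 0` gives the all-zero map.
#'
#' @param spec A [height_map_spec()].
#' @return A [height_map()].
#' @examples
#' hm <- gen_height_map(height_map_spec(n_pixels = 64, target_rq = 8.01))
#' rms_roughness(hm) # 8.01
#' @export
gen_height_map <- function(spec) {
  stopifnot(inherits(spec, "height_map_spec"))
  n <- spec$n_pixels
  z <- withr::with_seed(spec$seed, matrix(stats::rnorm(n * n), n, n))
  z <- fft_lowpass(z, spec$corr_length / spec$pixel_size)
  z <- z - mean(z)
  rms <- sqrt(mean(z^2))
  z <- if (rms > 0 && spec$target_rq > 0) z * (spec$target_rq / rms)
       else matrix(0, n, n)
  height_map(z, spec$pixel_size)
}

#' Generate a fractional-Brownian surface by spectral synthesis
#'
#' Self-affine random surface with Hurst exponent `H`, synthesized by
#' shaping white Gaussian Fourier coefficients with the power spectrum
#' `P(f) ~ f^(-2(H + 1))`. The expected fractal dimension of such a
#' surface is `D = 3 - H`, which makes it the independent oracle for the
#' box-counting dimension estimator. Synthesis runs on an `oversample`-fold
#' finer lattice that is then point-sampled, so the returned grid keeps
#' close-to-theoretical roughness at the pixel scale instead of the
#' band-limited smoothness a same-size synthesis would have.
#'
#' @param n_pixels Side length (power of 2 recommended), >= 16.
#' @param hurst Hurst exponent in (0, 1).
#' @param seed Integer seed.
#' @param pixel_size Lateral sampling, nm/pixel.
#' @param oversample Synthesis refinement factor (default 2).
#' @return A [height_map()] (unit-variance heights).
#' @export
gen_fbm_surface <- function(n_pixels = 128L, hurst = 0.5, seed = 1L,
                            pixel_size = 2000 / n_pixels, oversample = 2L) {
  stopifnot(n_pixels >= 16, hurst > 0, hurst < 1, oversample >= 1)
  n <- as.integer(n_pixels) * as.integer(oversample)
  f <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / n
  fx <- matrix(f, n, n)
  fy <- t(fx)
  fr <- sqrt(fx^2 + fy^2)
  amp <- ifelse(fr > 0, fr^(-(hurst + 1)), 0)
  z <- withr::with_seed(seed, {
    noise <- matrix(complex(real = stats::rnorm(n * n),
                            imaginary = stats::rnorm(n * n)), n, n)
    Re(stats::fft(noise * amp, inverse = TRUE)) / n^2
  })
  idx <- seq(1L, n, by = as.integer(oversample))
  z <- z[idx, idx]
  z <- z - mean(z)
  s <- sqrt(mean(z^2))
  if (s > 0) z <- z / s
  height_map(z, pixel_size)
}
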