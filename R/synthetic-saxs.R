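#' Specify a synthetic lamellar stack
#'
#' Forward model for two-phase semicrystalline lamellae: alternating
#' crystalline/amorphous layers with Gaussian thickness jitter (truncated at
#' 0.2 x mean so all layers stay positive), unit/zero density contrast, and
#' an optional power-law background mimicking mass-fractal scattering.
#'
#' @param d_c_mean Mean crystalline layer thickness, nm, > 0.
#' @param d_a_mean Mean amorphous layer thickness, nm, > 0.
#' @param sigma_c,sigma_a Layer-thickness standard deviations, nm, >= 0.
#' @param n_repeats Number of lamellar repeats, integer >= 20.
#' @param alpha_bg Background power-law exponent (typically in (-3, -1)).
#' @param bg_amplitude Background scale, arbitrary units, >= 0 (default 0:
#'   no background).
#' @return An object of class `stack_spec`. The ground-truth long period is
#'   `d_c_mean + d_a_mean`.
#' @examples
#' stack_spec(d_c_mean = 5.33, d_a_mean = 5.55,
#'            sigma_c = 0.533, sigma_a = 0.555)
#' @export
stack_spec <- function(d_c_mean, d_a_mean, sigma_c = 0, sigma_a = 0,
                       n_repeats = 32L, alpha_bg = -2, bg_amplitude = 0) {
  stopifnot(d_c_mean > 0, d_a_mean > 0, sigma_c >= 0, sigma_a >= 0,
            n_repeats >= 20, bg_amplitude >= 0)
  structure(
    list(d_c_mean = d_c_mean, d_a_mean = d_a_mean,
         sigma_c = sigma_c, sigma_a = sigma_a,
         n_repeats = as.integer(n_repeats),
         alpha_bg = alpha_bg, bg_amplitude = bg_amplitude),
    class = "stack_spec"
  )
}

# Gaussian thickness jitter truncated at +-0.2 * mean (rejection sampling)
rtrunc_thickness <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  lo <- 0.8 * mean
  hi <- 1.2 * mean
  out <- stats::rnorm(n, mean, sd)
  bad <- out < lo | out > hi
  while (any(bad)) {
    out[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- out < lo | out > hi
  }
  out
}

#' Generate lamellar scattering with a real-space brute-force oracle
#'
#' Builds `n_realizations` random one-dimensional two-phase density
#' profiles (crystalline = 1, amorphous = 0) on a fine grid (step <= 0.05
#' nm) and returns both sides of the correlation-function identity:
#'
#' * `cf`: the ensemble-averaged one-dimensional correlation function
#'   computed by direct autocorrelation of the mean-subtracted profile,
#'   normalized to 1 at r = 0 - the brute-force oracle the reciprocal-space
#'   pipeline is checked against;
#' * `curve`: the orientationally weighted intensity
#'   `I(q) = I_1D(q) / q^2` from the ensemble-averaged squared Fourier
#'   magnitude of the profile, plus `bg_amplitude * q^alpha_bg` background.
#'
#' @param spec A [stack_spec()].
#' @param q_grid Scattering vector grid in 1/Angstrom, positive and
#'   increasing; must reach past the long-period peak
#'   (`q_max >= 4 * pi / d`).
#' @param n_realizations Number of independent stack realizations to
#'   average, >= 1.
#' @param seed Integer seed; identical seeds give identical output.
#' @param r_max Maximum lag of the oracle correlation function, nm
#'   (default 3 long periods).
#' @param dx Real-space grid step, nm, at most 0.05.
#' @return A list with `curve` (a [scattering_curve()]), `cf` (a
#'   [correlation_fn()], the oracle), and `truth` (list of ground-truth
#'   `d`, `d_c`, `d_a`, `alpha_bg`).
#' @examples
#' sp <- stack_spec(5.33, 5.55, 0.533, 0.555, n_repeats = 24)
#' sim <- gen_lamellar_scattering(sp, seq(0.01, 0.25, by = 0.002),
#'                                n_realizations = 4, seed = 7)
#' @export
gen_lamellar_scattering <- function(spec, q_grid, n_realizations = 16L,
                                    seed = 1L, r_max = NULL, dx = 0.05) {
  stopifnot(inherits(spec, "stack_spec"))
  q_grid <- as.numeric(q_grid)
  if (any(q_grid <= 0) || any(diff(q_grid) <= 0)) {
    stop("`q_grid` must be positive and strictly increasing", call. = FALSE)
  }
  if (n_realizations < 1L) stop("`n_realizations` must be >= 1",
                                call. = FALSE)
  if (dx > 0.05) stop("`dx` must be <= 0.05 nm", call. = FALSE)
  d_long <- spec$d_c_mean + spec$d_a_mean
  if (max(q_grid) < 4 * pi / (10 * d_long)) {
    stop("q range too narrow to resolve the long period", call. = FALSE)
  }
  if (is.null(r_max)) r_max <- 3 * d_long
  n_lag <- floor(r_max / dx)
  q_nm <- q_grid * 10 # 1/Angstrom -> 1/nm

  withr::with_seed(seed, {
    acf_sum <- numeric(n_lag + 1L)
    I1d_sum <- numeric(length(q_nm))
    for (real in seq_len(n_realizations)) {
      th_c <- rtrunc_thickness(spec$n_repeats, spec$d_c_mean, spec$sigma_c)
      th_a <- rtrunc_thickness(spec$n_repeats, spec$d_a_mean, spec$sigma_a)
      # alternate crystalline/amorphous layers on the fine grid
      n_px_c <- pmax(1L, round(th_c / dx))
      n_px_a <- pmax(1L, round(th_a / dx))
      rho <- rep(
        rep(c(1, 0), spec$n_repeats),
        as.vector(rbind(n_px_c, n_px_a))
      )
      rho <- rho - mean(rho)
      N <- length(rho)
      # direct non-circular autocorrelation (standard 1/N normalization)
      acf_sum <- acf_sum + vapply(0:n_lag, function(l) {
        sum(rho[seq_len(N - l)] * rho[seq_len(N - l) + l]) / N
      }, numeric(1L))
      # squared Fourier magnitude at the requested q, per unit length
      x <- (seq_len(N) - 1L) * dx
      amp <- vapply(q_nm, function(q) {
        abs(sum(rho * exp(1i * q * x)))^2
      }, numeric(1L))
      I1d_sum <- I1d_sum + amp * dx^2 / (N * dx)
    }
    acf_mean <- acf_sum / n_realizations
    I1d <- I1d_sum / n_realizations
  })

  L <- acf_mean / acf_mean[1L]
  intensity <- I1d / q_nm^2 +
    spec$bg_amplitude * q_grid^spec$alpha_bg
  list(
    curve = scattering_curve(q_grid, intensity),
    cf = correlation_fn(r = (0:n_lag) * dx, L = L),
    truth = list(d = d_long, d_c = spec$d_c_mean, d_a = spec$d_a_mean,
                 alpha_bg = spec$alpha_bg)
  )
}
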