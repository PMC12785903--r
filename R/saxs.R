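#' Construct a scattering curve
#'
#' Background-subtracted small-angle scattering data: scattering vector `q`
#' in 1/Angstrom (typical measured window 0.010--0.25) and intensity `I` in
#' arbitrary units.
#'
#' @param q Scattering vector, 1/Angstrom, positive and strictly
#'   increasing, at least 30 points.
#' @param I Intensity, same length as `q`.
#' @return An object of class `scattering_curve`.
#' @export
scattering_curve <- function(q, I) {
  q <- as.numeric(q)
  I <- as.numeric(I)
  if (length(q) != length(I)) {
    stop("`q` and `I` must have the same length", call. = FALSE)
  }
  if (length(q) < 30L) {
    stop("need at least 30 (q, I) points", call. = FALSE)
  }
  if (any(q <= 0) || any(diff(q) <= 0)) {
    stop("`q` must be positive and strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(I))) stop("`I` must be finite", call. = FALSE)
  structure(list(q = q, I = I), class = "scattering_curve")
}

#' @export
print.scattering_curve <- function(x, ...) {
  cat(sprintf("<scattering_curve> %d points, q = %.4g..%.4g 1/Angstrom\n",
              length(x$q), min(x$q), max(x$q)))
  invisible(x)
}

#' Construct a correlation function
#'
#' Normalized one-dimensional correlation function `L(r)` on a uniform
#' real-space grid `r` (nm, from 0), with `L(0) = 1`.
#'
#' @param r Real-space distance, nm, uniform grid starting at 0.
#' @param L Correlation values, `L[1] = 1` within 1e-6.
#' @return An object of class `correlation_fn`.
#' @export
correlation_fn <- function(r, L) {
  r <- as.numeric(r)
  L <- as.numeric(L)
  if (length(r) != length(L)) {
    stop("`r` and `L` must have the same length", call. = FALSE)
  }
  if (r[1L] != 0) stop("`r` must start at 0", call. = FALSE)
  dr <- diff(r)
  if (any(abs(dr - dr[1L]) > 1e-9 * dr[1L])) {
    stop("`r` grid must be uniform", call. = FALSE)
  }
  if (abs(L[1L] - 1) > 1e-6) {
    stop("L(0) must equal 1 (normalization)", call. = FALSE)
  }
  structure(list(r = r, L = L), class = "correlation_fn")
}

#' @export
print.correlation_fn <- function(x, ...) {
  cat(sprintf("<correlation_fn> %d points, r = 0..%.3g nm\n",
              length(x$r), max(x$r)))
  invisible(x)
}

#' One-dimensional correlation function of a scattering curve
#'
#' Computes the normalized correlation function
#' `L(r) = Int I(q) q^2 cos(q r) dq / Int I(q) q^2 dq`
#' by trapezoidal quadrature. The measured window is extended on both
#' sides using the standard correlation-function conventions:
#'
#' * low q: linear-in-`q^2` fit through the first `n_low` points,
#'   extrapolated to q = 0;
#' * high q: Porod fit `I = K / q^4 + b` over the top 20 percent of the q
#'   range; the flat background `b` is subtracted from the whole curve and
#'   the `K / q^4` tail is extended to `q_tail` (default 2 1/Angstrom).
#'
#' q is supplied in 1/Angstrom; `r` is reported in nm.
#'
#' @param curve A [scattering_curve()].
#' @param r_max Maximum real-space distance, nm.
#' @param n_r Number of r-grid points (uniform from 0).
#' @param n_low Points used for the low-q extrapolation (default 5).
#' @param q_tail Porod-tail extension limit, 1/Angstrom (default 2).
#' @return A [correlation_fn()].
#' @export
correlation_function <- function(curve, r_max = 40, n_r = 401L,
                                 n_low = 5L, q_tail = 2) {
  stopifnot(inherits(curve, "scattering_curve"))
  if (r_max <= 0) stop("`r_max` must be > 0", call. = FALSE)
  q <- curve$q
  I <- curve$I
  n <- length(q)

  # Porod region: top 20 % of the measured q range
  hi <- q >= q[1L] + 0.8 * (q[n] - q[1L])
  if (sum(hi) < 3L) hi <- seq(n - 2L, n) >= 1 # degenerate grids
  pf <- stats::lm.fit(cbind(1, q[hi]^-4), I[hi])
  b <- pf$coefficients[1L]
  K <- pf$coefficients[2L]
  if (!is.finite(K) || K <= 0) {
    stop("Porod fit failed (K <= 0): intensity tail is not Porod-like",
         call. = FALSE)
  }
  I_sub <- I - b

  # low-q: linear in q^2 through the first n_low (background-subtracted)
  lf <- stats::lm.fit(cbind(1, q[seq_len(n_low)]^2), I_sub[seq_len(n_low)])
  a0 <- lf$coefficients[1L]
  a2 <- lf$coefficients[2L]

  # assembled q grid (1/Angstrom): extrapolated head, data, Porod tail.
  # Tail spacing is tied to r_max so q*r phase steps stay small.
  q_head <- seq(0, q[1L], length.out = 64L)
  q_head <- q_head[-length(q_head)]
  I_head <- a0 + a2 * q_head^2
  dq_tail <- min(0.02 / r_max, 0.002)
  q_tl <- seq(q[n], q_tail, by = dq_tail)[-1L]
  I_tl <- K / q_tl^4
  qq <- c(q_head, q, q_tl)
  II <- c(I_head, I_sub, I_tl)

  q_nm <- qq * 10 # 1/Angstrom -> 1/nm, so q*r is dimensionless with r in nm
  w <- II * q_nm^2
  denom <- pracma::trapz(q_nm, w)
  if (denom <= 0) {
    stop("non-positive normalization integral", call. = FALSE)
  }
  r <- seq(0, r_max, length.out = n_r)
  L <- vapply(r, function(ri) {
    pracma::trapz(q_nm, w * cos(q_nm * ri)) / denom
  }, numeric(1L))
  correlation_fn(r, L)
}

# index of the first interior local minimum / maximum after `from`
first_local_extremum <- function(y, from = 2L, maximum = TRUE) {
  n <- length(y)
  for (i in seq(max(from, 2L), n - 1L)) {
    if (maximum && y[i] >= y[i - 1L] && y[i] > y[i + 1L]) return(i)
    if (!maximum && y[i] <= y[i - 1L] && y[i] < y[i + 1L]) return(i)
  }
  NA_integer_
}

# parabolic refinement of an extremum on a uniform grid
refine_extremum <- function(x, y, i) {
  d1 <- (y[i + 1L] - y[i - 1L]) / 2
  d2 <- y[i + 1L] - 2 * y[i] + y[i - 1L]
  if (d2 == 0) return(x[i])
  x[i] - d1 / d2 * (x[2L] - x[1L])
}

#' Lamellar thicknesses from a correlation function
#'
#' Extracts the long period `d` (position of the first interior local
#' maximum of `L(r)`), and splits it into the two layer thicknesses by the
#' standard linear-fit construction: a line is fitted to the initial decay
#' of `L(r)` (where it descends through \[0.8, 0.3\]) and intersected with
#' the horizontal baseline through the first minimum; the intersection
#' abscissa is the thinner layer thickness, the complement `d - thinner`
#' the thicker one. Which physical layer (crystalline or amorphous) is the
#' thinner one cannot be decided from `L(r)` alone, so the assignment is an
#' explicit caller choice.
#'
#' @param cf A [correlation_fn()] with at least one interior local maximum.
#' @param assign_thinner_to `"d_c"` (default) or `"d_a"`: which layer the
#'   thinner thickness is assigned to.
#' @return A list of class `lamellar_result` with `d`, `d_a`, `d_c` (nm,
#'   `d = d_a + d_c` by construction), `thinner` (nm) and
#'   `baseline` (the first-minimum level).
#' @export
lamellar_params <- function(cf, assign_thinner_to = c("d_c", "d_a")) {
  stopifnot(inherits(cf, "correlation_fn"))
  assign_thinner_to <- match.arg(assign_thinner_to)
  r <- cf$r
  L <- cf$L
  i_min <- first_local_extremum(L, maximum = FALSE)
  # long-period peak: global maximum beyond the first minimum (small
  # ripples on the inter-lamellar plateau must not be mistaken for it)
  i_max <- if (is.na(i_min) || i_min >= length(L) - 1L) NA_integer_ else {
    i_min + which.max(L[(i_min + 1L):(length(L) - 1L)])
  }
  if (is.na(i_min) || is.na(i_max) ||
      L[i_max] < L[i_max - 1L] || L[i_max] < L[i_max + 1L]) {
    stop("no interior maximum in L(r): input is not lamellar", call. = FALSE)
  }
  d <- refine_extremum(r, L, i_max)
  baseline <- L[i_min]
  # linear fit to the initial decay where L descends through [0.8, 0.3]
  decay <- which(L <= 0.8 & L >= 0.3 & seq_along(L) <= i_min)
  if (length(decay) < 2L) {
    # very coarse grid: take the two points bracketing L = 0.55
    j <- which(L < 0.55)[1L]
    decay <- c(j - 1L, j)
  }
  lf <- stats::lm.fit(cbind(1, r[decay]), L[decay])
  thinner <- unname((baseline - lf$coefficients[1L]) / lf$coefficients[2L])
  if (!is.finite(thinner) || thinner <= 0 || thinner >= d) {
    stop("degenerate initial-decay construction", call. = FALSE)
  }
  thicker <- d - thinner
  if (assign_thinner_to == "d_c") {
    d_c <- thinner; d_a <- thicker
  } else {
    d_a <- thinner; d_c <- thicker
  }
  structure(
    list(d = d, d_a = d_a, d_c = d_c, thinner = thinner,
         baseline = baseline, assign_thinner_to = assign_thinner_to),
    class = "lamellar_result"
  )
}

#' @export
print.lamellar_result <- function(x, ...) {
  cat(sprintf("Lamellae: d = %.2f nm (d_a = %.2f, d_c = %.2f nm)\n",
              x$d, x$d_a, x$d_c))
  invisible(x)
}

#' Long period from the Lorentz-corrected peak position
#'
#' Secondary long-period estimate `d = 2 pi / q*`, with `q*` the position
#' of the maximum of the Lorentz-corrected intensity `I q^2` (parabolically
#' refined). Complements the first-maximum estimate of [lamellar_params()].
#'
#' @param curve A [scattering_curve()].
#' @return Long period in nm.
#' @export
bragg_long_period <- function(curve) {
  stopifnot(inherits(curve, "scattering_curve"))
  lor <- curve$I * curve$q^2
  i <- which.max(lor)
  if (i == 1L || i == length(lor)) {
    stop("Lorentz-corrected maximum lies on the window edge", call. = FALSE)
  }
  q_star <- refine_extremum(curve$q, lor, i)
  2 * pi / (10 * q_star) # 1/Angstrom -> nm
}

# r^2 of OLS y ~ x over index window [i, j] using prefix moments
window_r2 <- function(m, i, j) {
  f <- seg_fit(m, i, j)
  f$r_squared
}

#' Mass-fractal power-law exponent of a scattering curve
#'
#' Fits `log I` against `log q` by ordinary least squares inside a q
#' window and reports the power-law exponent `alpha` and the mass fractal
#' dimension `D_m = -alpha`, valid for `alpha` in (-3, -1) (flagged
#' otherwise, never clamped).
#'
#' With `q_range = NULL` (auto), the window is chosen as the longest
#' contiguous low-q stretch (at least `min_points` points, below the
#' lamellar interference peak located as the maximum of Lorentz-corrected
#' intensity `I q^2`) whose linear fit has `r^2 >= 0.99`.
#'
#' @param curve A [scattering_curve()] with positive intensities in the
#'   fit window.
#' @param q_range Numeric `c(q_lo, q_hi)` in 1/Angstrom, or `NULL` for
#'   automatic window selection.
#' @param min_points Minimum points in the fit window (default 6).
#' @return A list of class `fractal_result` with `alpha`, `D_m`,
#'   `fit_q_range`, `r_squared`, and `flag_outside_validity` (TRUE when
#'   `alpha` is outside (-3, -1)).
#' @examples
#' q <- seq(0.01, 0.25, length.out = 60)
#' fractal_exponent(scattering_curve(q, q^-2))
#' @export
fractal_exponent <- function(curve, q_range = NULL, min_points = 6L) {
  stopifnot(inherits(curve, "scattering_curve"))
  q <- curve$q
  I <- curve$I
  if (!is.null(q_range)) {
    sel <- which(q >= q_range[1L] & q <= q_range[2L])
    if (length(sel) < min_points) {
      stop("fewer than `min_points` points in the fit window", call. = FALSE)
    }
    if (any(I[sel] <= 0)) {
      stop("non-positive intensities in the fit window", call. = FALSE)
    }
    m <- seg_moments(log(q[sel]), log(I[sel]))
    f <- seg_fit(m, 1L, length(sel))
    window <- c(q[sel[1L]], q[sel[length(sel)]])
  } else {
    # restrict to below the lamellar peak of the Lorentz-corrected curve;
    # a peak counts only if clearly above both window edges, so smooth
    # power-law curves keep their full range
    lor <- I * q^2
    i_star <- which.max(lor)
    has_peak <- i_star > 1L && i_star < length(q) &&
      lor[i_star] >= 1.05 * max(lor[1L], lor[length(q)])
    upper <- if (has_peak) i_star else length(q)
    sel <- seq_len(upper)
    sel <- sel[I[sel] > 0]
    if (length(sel) < min_points) {
      stop("too few usable low-q points", call. = FALSE)
    }
    lx <- log(q[sel])
    ly <- log(I[sel])
    m <- seg_moments(lx, ly)
    best <- NULL
    ns <- length(sel)
    for (i in seq_len(ns - min_points + 1L)) {
      for (j in seq(i + min_points - 1L, ns)) {
        if (window_r2(m, i, j) >= 0.99) {
          len <- j - i + 1L
          if (is.null(best) || len > best$len) best <- list(i = i, j = j,
                                                            len = len)
        }
      }
    }
    if (is.null(best)) {
      stop("no low-q window with r^2 >= 0.99: supply `q_range` explicitly",
           call. = FALSE)
    }
    f <- seg_fit(m, best$i, best$j)
    window <- c(q[sel[best$i]], q[sel[best$j]])
  }
  alpha <- f$slope
  structure(
    list(alpha = alpha, D_m = -alpha, fit_q_range = window,
         r_squared = f$r_squared,
         flag_outside_validity = !(alpha > -3 && alpha < -1)),
    class = "fractal_result"
  )
}

#' @export
print.fractal_result <- function(x, ...) {
  cat(sprintf(
    "Power-law fit: alpha = %.3f, D_m = %.3f over q = %.4g..%.4g (r2 = %.4f)%s\n",
    x$alpha, x$D_m, x$fit_q_range[1L], x$fit_q_range[2L], x$r_squared,
    if (x$flag_outside_validity) " [outside (-3, -1) validity window]" else ""
  ))
  invisible(x)
}
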