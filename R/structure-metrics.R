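#' Construct a spectrum
#'
#' Two-column spectral data: abscissa `x` (wavenumber in 1/cm for FTIR,
#' degrees 2-theta for XRD, strictly monotone) and intensity/absorbance
#' `y`.
#'
#' @param x Abscissa, strictly monotone.
#' @param y Intensity, same length.
#' @return An object of class `spectrum_xy`.
#' @export
spectrum_xy <- function(x, y) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) {
    stop("`x` and `y` must have the same length", call. = FALSE)
  }
  if (length(x) < 2L) stop("need at least 2 points", call. = FALSE)
  d <- diff(x)
  if (!(all(d > 0) || all(d < 0))) {
    stop("`x` must be strictly monotone", call. = FALSE)
  }
  if (any(!is.finite(y))) stop("`y` must be finite", call. = FALSE)
  structure(list(x = x, y = y), class = "spectrum_xy")
}

#' @export
print.spectrum_xy <- function(x, ...) {
  cat(sprintf("<spectrum_xy> %d points, x = %g..%g\n",
              length(x$x), min(x$x), max(x$x)))
  invisible(x)
}

# ensure ascending abscissa
ascending <- function(spec) {
  if (spec$x[1L] > spec$x[length(spec$x)]) {
    spectrum_xy(rev(spec$x), rev(spec$y))
  } else {
    spec
  }
}

#' FTIR short-range order ratio (1047/1022)
#'
#' Band-intensity ratio of the 1047 1/cm (ordered/crystalline) to the
#' 1022 1/cm (amorphous) absorbance, after subtracting a linear baseline
#' anchored at the absorbances nearest 1200 and 800 1/cm. Higher values
#' indicate more short-range (double-helical) order.
#'
#' @param spec A [spectrum_xy()] covering 800--1200 1/cm.
#' @return The 1047/1022 intensity ratio (numeric scalar).
#' @export
short_range_order <- function(spec) {
  stopifnot(inherits(spec, "spectrum_xy"))
  spec <- ascending(spec)
  if (min(spec$x) > 800 || max(spec$x) < 1200) {
    stop("spectrum must cover 800-1200 1/cm", call. = FALSE)
  }
  at <- function(target) which.min(abs(spec$x - target))
  i800 <- at(800)
  i1200 <- at(1200)
  slope <- (spec$y[i1200] - spec$y[i800]) / (spec$x[i1200] - spec$x[i800])
  base <- spec$y[i800] + slope * (spec$x - spec$x[i800])
  yc <- spec$y - base
  denom <- yc[at(1022)]
  if (denom <= 0) {
    stop("non-positive corrected absorbance at 1022 1/cm", call. = FALSE)
  }
  yc[at(1047)] / denom
}

# rolling-ball (disk) morphological opening baseline.
# radius_x in abscissa units; the ball height is scaled so gently curved
# halos are followed while narrow peaks are bridged. Two passes: the first
# scales the ball to the full data range (dominated by sharp peaks), the
# second rescales it to the range of the first-pass envelope, which keeps
# the bridging arcs flat enough not to poke above the halo under peaks.
rolling_ball_once <- function(y, m, ball) {
  n <- length(y)
  pad <- function(v, left, right) c(rep(left, m), v, rep(right, m))
  yp <- pad(y, y[1L], y[n])
  erode <- vapply(seq_len(n), function(i) {
    min(yp[i:(i + 2L * m)] - ball)
  }, numeric(1L))
  ep <- pad(erode, erode[1L], erode[n])
  vapply(seq_len(n), function(i) {
    max(ep[i:(i + 2L * m)] + ball)
  }, numeric(1L))
}

rolling_ball_baseline <- function(x, y, radius_x) {
  dx <- x[2L] - x[1L]
  m <- max(1L, round(radius_x / dx))
  u <- (-m:m) * dx
  shape <- sqrt(pmax(radius_x^2 - u^2, 0))
  scale_of <- function(v) (max(v) - min(v)) / radius_x
  b1 <- rolling_ball_once(y, m, scale_of(y) * shape)
  s2 <- scale_of(b1)
  if (s2 <= 0) return(b1)
  rolling_ball_once(y, m, s2 * shape)
}

#' XRD relative crystallinity
#'
#' Percent of diffracted intensity in sharp (crystalline) peaks above the
#' amorphous halo. The pattern is smoothed with a Savitzky-Golay filter
#' (11-point window, order 3), the amorphous halo is estimated by a
#' rolling-ball minimum envelope (default radius 5 degrees 2-theta), and
#' `Rc = 100 * area(smoothed - halo) / area(smoothed above zero)` with
#' trapezoidal areas. Because the halo envelope is a numerical stand-in
#' for profile-fitting software, absolute values are comparable only
#' between patterns analyzed the same way.
#'
#' @param spec A [spectrum_xy()] covering the 4--40 degrees 2-theta window.
#' @param ball_radius Rolling-ball radius in degrees 2-theta (default 5).
#' @param sg_window,sg_order Savitzky-Golay window length (odd) and
#'   polynomial order.
#' @return Relative crystallinity in percent.
#' @export
relative_crystallinity <- function(spec, ball_radius = 5,
                                   sg_window = 11L, sg_order = 3L) {
  stopifnot(inherits(spec, "spectrum_xy"))
  spec <- ascending(spec)
  if (min(spec$x) > 4 || max(spec$x) < 40) {
    stop("pattern must cover 4-40 degrees 2-theta", call. = FALSE)
  }
  y <- signal::sgolayfilt(spec$y, p = sg_order, n = sg_window)
  y <- pmax(y, 0)
  base <- pmax(rolling_ball_baseline(spec$x, y, ball_radius), 0)
  base <- pmin(base, y)
  total <- pracma::trapz(spec$x, y)
  if (total <= 0) stop("pattern has no positive area", call. = FALSE)
  crystalline <- pracma::trapz(spec$x, y - base)
  100 * crystalline / total
}

#' RMS roughness of a height map
#'
#' `Rq = sqrt(mean((h - mean(h))^2))` over all pixels.
#'
#' @param map A [height_map()] of at least 16 x 16 pixels.
#' @return Rq in nm.
#' @export
rms_roughness <- function(map) {
  stopifnot(inherits(map, "height_map"))
  h <- map$heights
  if (nrow(h) < 16L) stop("need at least a 16 x 16 grid", call. = FALSE)
  sqrt(mean((h - mean(h))^2))
}

#' Gray-level co-occurrence texture features
#'
#' Quantizes the heights min-max into `levels` gray levels, accumulates
#' symmetric co-occurrence matrices for the given pixel offsets, averages
#' and normalizes them to probabilities P, and reports
#' `energy = sum(P^2)`, `contrast = sum((i - j)^2 P)`,
#' `homogeneity = sum(P / (1 + |i - j|))`, and
#' `entropy = -sum(P log P)` (natural log; 0 log 0 = 0).
#' A constant map occupies a single level: energy 1, contrast 0,
#' homogeneity 1, entropy 0.
#'
#' @param map A [height_map()].
#' @param levels Number of gray levels, >= 2 (default 16).
#' @param offsets List of integer `c(drow, dcol)` pixel offsets; default
#'   the four standard directions `(0,1), (1,0), (1,1), (1,-1)`.
#' @return A list of class `glcm_features` with `energy`, `contrast`,
#'   `homogeneity`, `entropy`.
#' @export
glcm_features <- function(map, levels = 16L,
                          offsets = list(c(0L, 1L), c(1L, 0L),
                                         c(1L, 1L), c(1L, -1L))) {
  stopifnot(inherits(map, "height_map"))
  if (levels < 2L) stop("`levels` must be >= 2", call. = FALSE)
  h <- map$heights
  rng <- max(h) - min(h)
  g <- if (rng == 0) {
    matrix(1L, nrow(h), ncol(h))
  } else {
    matrix(pmin(levels, floor((h - min(h)) / rng * levels) + 1L),
           nrow(h), ncol(h))
  }
  P <- matrix(0, levels, levels)
  for (off in offsets) {
    dr <- off[1L]; dc <- off[2L]
    if (abs(dr) >= nrow(g) || abs(dc) >= ncol(g)) {
      stop("map smaller than offset span", call. = FALSE)
    }
    rows <- seq_len(nrow(g) - abs(dr))
    cols <- seq_len(ncol(g) - abs(dc))
    r2 <- rows + abs(dr)
    c2 <- if (dc >= 0) cols + dc else cols + abs(dc)
    a <- if (dc >= 0) g[rows, cols, drop = FALSE] else
      g[rows, c2, drop = FALSE]
    b <- if (dc >= 0) g[r2, c2, drop = FALSE] else
      g[r2, cols, drop = FALSE]
    tab <- table(factor(a, levels = seq_len(levels)),
                 factor(b, levels = seq_len(levels)))
    M <- matrix(as.numeric(tab), levels, levels)
    P <- P + M + t(M) # symmetric accumulation
  }
  P <- P / sum(P)
  ij <- abs(row(P) - col(P))
  nz <- P > 0
  structure(
    list(
      energy = sum(P^2),
      contrast = sum(ij^2 * P),
      homogeneity = sum(P / (1 + ij)),
      entropy = -sum(P[nz] * log(P[nz]))
    ),
    class = "glcm_features"
  )
}

#' @export
print.glcm_features <- function(x, ...) {
  cat(sprintf(
    "GLCM: energy %.4f, contrast %.4f, homogeneity %.4f, entropy %.4f\n",
    x$energy, x$contrast, x$homogeneity, x$entropy
  ))
  invisible(x)
}

# halve both matrix dimensions, taking fun (pmin/pmax) over 2 x 2 blocks
reduce2 <- function(m, fun) {
  n <- nrow(m)
  m1 <- fun(m[seq(1L, n, 2L), , drop = FALSE],
            m[seq(2L, n, 2L), , drop = FALSE])
  t(fun(t(m1)[seq(1L, n, 2L), , drop = FALSE],
        t(m1)[seq(2L, n, 2L), , drop = FALSE]))
}

#' Differential box-counting fractal dimension of a surface
#'
#' Differential box counting: for dyadic box sizes `s` up to `side/4`, the
#' surface is tiled with `s x s` columns of height
#' `h_box = s * range(h) / side`, each column contributing
#' `max(1, ceiling((h_max - h_min) / h_box))` boxes; the dimension is the
#' least-squares slope of `ln N(s)` against `ln(1/s)`. A smooth (planar)
#' surface gives 2; self-affine roughness raises the dimension toward 3.
#' A globally flat map has no height range and returns 2 by convention,
#' with a flag.
#'
#' Counts at pixel-scale boxes are systematically depressed on sampled
#' surfaces (a lattice grid cannot resolve sub-pixel height variation, so
#' small-box ranges fall short of their continuum values and drag the
#' fitted slope toward 2). The default scaling range therefore starts at
#' `min_box = max(2, side/32)`, i.e. pixel-scale boxes are excluded once
#' the grid is large enough to afford it; `min_box = 2` restores the full
#' dyadic ladder.
#'
#' @param map A [height_map()] with square side >= 64, side a power of 2.
#' @param min_box Smallest box size used in the slope fit (power of 2).
#' @return A list of class `box_dimension` with `dimension`, `sizes`,
#'   `counts`, `flag_flat`.
#' @export
box_fractal_dimension <- function(map, min_box = NULL) {
  stopifnot(inherits(map, "height_map"))
  h <- map$heights
  side <- nrow(h)
  if (side < 64L) stop("need a square grid with side >= 64", call. = FALSE)
  if (bitwAnd(side, side - 1L) != 0L) {
    stop("side must be a power of 2", call. = FALSE)
  }
  if (is.null(min_box)) min_box <- max(2L, side %/% 32L)
  rng <- max(h) - min(h)
  if (rng == 0) {
    return(structure(list(dimension = 2, sizes = integer(0),
                          counts = numeric(0), flag_flat = TRUE),
                     class = "box_dimension"))
  }
  sizes_all <- 2^(1:floor(log2(side / 4)))
  mx <- h
  mn <- h
  counts_all <- vapply(seq_along(sizes_all), function(i) {
    mx <<- reduce2(mx, pmax)
    mn <<- reduce2(mn, pmin)
    h_box <- sizes_all[i] * rng / side
    sum(pmax(1, ceiling((mx - mn) / h_box)))
  }, numeric(1L))
  keep <- sizes_all >= min_box
  if (sum(keep) < 2L) {
    stop("fewer than 2 box sizes in the scaling range", call. = FALSE)
  }
  fit <- stats::lm.fit(cbind(1, log(1 / sizes_all[keep])),
                       log(counts_all[keep]))
  structure(
    list(dimension = unname(fit$coefficients[2L]), sizes = sizes_all[keep],
         counts = counts_all[keep], flag_flat = FALSE),
    class = "box_dimension"
  )
}

#' @export
print.box_dimension <- function(x, ...) {
  cat(sprintf("Box-counting dimension: %.3f%s\n", x$dimension,
              if (x$flag_flat) " (flat surface, by convention)" else ""))
  invisible(x)
}

#' All surface texture descriptors at once
#'
#' Convenience wrapper returning RMS roughness, the four GLCM features and
#' the box-counting fractal dimension of one height map.
#'
#' @param map A [height_map()].
#' @param levels GLCM gray levels (default 16).
#' @return A list of class `texture_result` with `Rq`, `energy`,
#'   `contrast`, `homogeneity`, `entropy`, `fractal_dimension`.
#' @export
texture_metrics <- function(map, levels = 16L) {
  g <- glcm_features(map, levels = levels)
  structure(
    list(Rq = rms_roughness(map),
         energy = g$energy, contrast = g$contrast,
         homogeneity = g$homogeneity, entropy = g$entropy,
         fractal_dimension = box_fractal_dimension(map)$dimension),
    class = "texture_result"
  )
}

#' @export
print.texture_result <- function(x, ...) {
  cat(sprintf(
    "Rq %.2f nm | energy %.4f contrast %.4f homogeneity %.4f entropy %.4f | D %.3f\n",
    x$Rq, x$energy, x$contrast, x$homogeneity, x$entropy,
    x$fractal_dimension
  ))
  invisible(x)
}
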