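#' Generate a synthetic spectrum
#'
#' Sum of Gaussian peaks on a linear baseline with optional seeded Gaussian
#' noise, used as the controllable test input for the FTIR short-range
#' order ratio and the XRD relative crystallinity.
#'
#' @param peaks Data frame (or list coercible to one) with columns
#'   `center`, `height`, `width` (Gaussian standard deviation, > 0), one
#'   row per peak; may have zero rows.
#' @param x_grid Abscissa grid (wavenumber in 1/cm for FTIR, degrees
#'   2-theta for XRD), strictly monotone.
#' @param baseline Numeric `c(slope, intercept)` of the linear baseline.
#' @param noise_sd Gaussian noise standard deviation (default 0).
#' @param seed Integer seed (used only when `noise_sd > 0`).
#' @return A [spectrum_xy()].
#' @examples
#' gen_spectrum(data.frame(center = 1047, height = 1, width = 10),
#'              x_grid = seq(800, 1200, by = 1))
#' @export
gen_spectrum <- function(peaks, x_grid, baseline = c(0, 0), noise_sd = 0,
                         seed = 1L) {
  peaks <- as.data.frame(peaks)
  if (nrow(peaks) > 0L) {
    stopifnot(all(c("center", "height", "width") %in% names(peaks)))
    if (any(peaks$width <= 0)) stop("peak widths must be > 0", call. = FALSE)
  }
  x_grid <- as.numeric(x_grid)
  if (length(x_grid) < 2L) stop("empty or degenerate grid", call. = FALSE)
  d <- diff(x_grid)
  if (!(all(d > 0) || all(d < 0))) {
    stop("`x_grid` must be strictly monotone", call. = FALSE)
  }
  y <- baseline[1L] * x_grid + baseline[2L]
  for (i in seq_len(nrow(peaks))) {
    y <- y + peaks$height[i] *
      exp(-(x_grid - peaks$center[i])^2 / (2 * peaks$width[i]^2))
  }
  if (noise_sd > 0) {
    y <- withr::with_seed(seed,
                          y + stats::rnorm(length(y), 0, noise_sd))
  }
  spectrum_xy(x_grid, y)
}
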