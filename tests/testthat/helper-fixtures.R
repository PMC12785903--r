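# Shared fixtures: kinetic parameter sets and synthetic spectra used across
# test files. All values are generator ground truths.

# two-phase kinetic parameters of the high-SI ternary complex
ternary_phases <- function() {
  list(
    phase_spec(k = 2.43e-2, C_inf = 60.21, t_end = 200),
    phase_spec(k = 1.44e-2, C_inf = 61.06, t_end = 540)
  )
}

# two-phase kinetic parameters of the plain amylopectin paste
paste_phases <- function() {
  list(
    phase_spec(k = 7.89e-2, C_inf = 89.39, t_end = 120),
    phase_spec(k = 3.20e-2, C_inf = 90.13, t_end = 540)
  )
}

# XRD pattern with a broad amorphous halo and sharp crystalline peaks whose
# in-window area fraction is exactly `frac_percent`
xrd_fixture <- function(frac_percent = 23.7, x = seq(4, 40, by = 0.05)) {
  gauss_area <- function(c0, h, s) {
    h * s * sqrt(2 * pi) *
      (stats::pnorm((max(x) - c0) / s) - stats::pnorm((min(x) - c0) / s))
  }
  halo <- data.frame(center = 21, height = 100, width = 6)
  a_halo <- gauss_area(21, 100, 6)
  centers <- c(13, 17, 20, 23)
  hts_rel <- c(1.2, 1.0, 0.9, 0.88)
  w <- 0.25
  a_rel <- gauss_area(centers, hts_rel, w)
  scale <- (frac_percent / (100 - frac_percent)) * a_halo / sum(a_rel)
  peaks <- data.frame(center = centers, height = hts_rel * scale, width = w)
  list(spectrum = gen_spectrum(rbind(halo, peaks), x),
       halo_only = gen_spectrum(halo, x),
       frac = frac_percent)
}

# FTIR spectrum with prescribed 1047/1022 corrected-intensity ratio; narrow
# peaks so cross-contribution between the two bands is negligible
ftir_fixture <- function(ratio, baseline = c(0, 0),
                         x = seq(780, 1220, by = 1)) {
  peaks <- data.frame(center = c(1047, 1022), height = c(ratio, 1),
                      width = 5)
  gen_spectrum(peaks, x, baseline = baseline)
}
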