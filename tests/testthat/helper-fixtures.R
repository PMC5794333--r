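# shared fixture builders; small grids keep single-purpose tests fast while
# quantification tests use the full default resolution

fast_cfg <- function(..., n_points = 16384) {
  spectrum_sim_config(..., n_points = n_points)
}

# analytic Lorentzian tail mass inside +/- w of the centre (unit total area)
lorentz_capture <- function(w, fwhm) {
  (2 / pi) * atan(2 * w / fwhm)
}

# same, after subtracting the linear baseline through the window endpoints:
# the baseline removes a 2w-wide trapezoid of height f(w)
lorentz_capture_baseline <- function(w, fwhm) {
  g <- fwhm / 2
  lorentz_capture(w, fwhm) - 2 * w * (g / pi) / (w^2 + g^2)
}

toy_anova_data <- function() {
  tibble::tibble(
    value = c(1, 2, 3, 2, 3, 4, 6, 7, 8),
    group = rep(c("a", "b", "c"), each = 3)
  )
}
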