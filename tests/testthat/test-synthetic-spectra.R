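test_that("equal-molar, equal-proton peaks have unit area ratio and zero input gives a flat baseline", {
  cfg <- fast_cfg()
  s <- simulate_spectrum(c(GB = 0.002), standard_conc = 0.002, cfg = cfg)
  a_gb <- integrate_peak(s, 3.27, 0.01)
  a_std <- integrate_peak(s, 0, 0.01)
  expect_equal(a_gb / a_std, 1, tolerance = 0.01)

  flat <- simulate_spectrum(c(GB = 0), standard_conc = 0, cfg = cfg)
  expect_true(all(flat$intensity == 0))
})

test_that("simulated peak area is proportional to concentration x proton count", {
  # slope test over 3 concentrations against the analytic Lorentzian area
  cfg <- fast_cfg(n_points = 32768)
  concs <- c(0.001, 0.002, 0.004)
  w <- 0.04
  capture <- lorentz_capture(w, cfg$linewidth / cfg$spectrometer_freq)
  areas <- vapply(concs, function(cc) {
    s <- simulate_spectrum(c(GB = cc), standard_conc = 0, cfg = cfg)
    # raw trapezoid without baseline, to compare against the analytic mass
    sel <- s$ppm >= 3.27 - w & s$ppm <= 3.27 + w
    x <- rev(s$ppm[sel]); y <- rev(s$intensity[sel])
    sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
  }, 1)
  expected <- concs * 9 * capture
  expect_equal(areas, expected, tolerance = 1e-3) # trapezoid discretisation
  # doubling concentration doubles area to high accuracy
  expect_equal(areas[2] / areas[1], 2, tolerance = 1e-6)
  expect_equal(areas[3] / areas[2], 2, tolerance = 1e-6)
})

test_that("unknown solutes and invalid configs are rejected", {
  expect_error(simulate_spectrum(c(bogus = 1), 0.5), "not in library")
  expect_error(simulate_spectrum(c(GB = -1), 0.5), ">= 0")
  expect_error(spectrum_sim_config(ppm_min = 5, ppm_max = 1), "ppm_min")
  expect_error(spectrum_sim_config(linewidth = 0), "linewidth")
})

test_that("noise is reproducible under a seed and absent without one", {
  cfg <- fast_cfg(n_points = 4096, noise_sd = 0.01, seed = 42)
  s1 <- simulate_spectrum(c(GB = 0.001), 0.001, cfg = cfg)
  s2 <- simulate_spectrum(c(GB = 0.001), 0.001, cfg = cfg)
  expect_identical(s1$intensity, s2$intensity)
  cfg3 <- fast_cfg(n_points = 4096, noise_sd = 0.01, seed = 43)
  s3 <- simulate_spectrum(c(GB = 0.001), 0.001, cfg = cfg3)
  expect_false(identical(s1$intensity, s3$intensity))
})

test_that("multiplets follow the binomial intensity pattern and conserve area", {
  lib <- tibble::tibble(
    solute = c("X", "TMSP"), shift = c(3.0, 0.0),
    multiplicity = c("triplet", "singlet"), j_hz = c(8, NA),
    n_protons = c(3L, 9L), quant = c(TRUE, TRUE), c13_split = FALSE,
    label = NA_character_
  )
  cfg <- fast_cfg(n_points = 32768)
  s <- simulate_spectrum(c(X = 0.004), standard_conc = 0, library = lib, cfg = cfg)
  pk <- detect_peaks(s)
  expect_equal(nrow(pk), 3) # 1:2:1 triplet resolved
  # outer lines half the central height
  expect_equal(pk$height[1] / pk$height[2], 0.5, tolerance = 0.02)
  # total multiplet area equals the singlet-equivalent area
  off <- 8 / cfg$spectrometer_freq
  total <- sum(vapply(3.0 + c(-off, 0, off), function(ctr) {
    integrate_peak(s, ctr, 0.004)
  }, 1))
  singlet_lib <- lib
  singlet_lib$multiplicity <- "singlet"
  s2 <- simulate_spectrum(c(X = 0.004), 0, library = singlet_lib, cfg = cfg)
  expect_equal(total, integrate_peak(s2, 3.0, 0.004), tolerance = 0.02)
})

test_that("labelled GB splits into satellites that conserve total area", {
  cfg <- fast_cfg(n_points = 32768)
  # no label: identical to the plain simulator
  s0 <- simulate_labeled_spectrum(0.003, 0, c(Ect = 0.001), cfg = cfg,
                                  standard_conc = 0.005)
  s_ref <- simulate_spectrum(c(GB = 0.003, Ect = 0.001), 0.005, cfg = cfg)
  expect_equal(s0$intensity, s_ref$intensity)

  # label conservation: central + satellites at equal split = unlabelled at total
  s_half <- simulate_labeled_spectrum(0.002, 0.002, cfg = cfg, standard_conc = 0.004)
  off <- 144 / (2 * cfg$spectrometer_freq)
  a_central <- integrate_peak(s_half, 3.27, 0.006)
  a_sat <- integrate_peak(s_half, 3.27 - off, 0.006) +
    integrate_peak(s_half, 3.27 + off, 0.006)
  expect_equal(a_central, a_sat, tolerance = 0.01)

  # full-axis mass is conserved: splitting redistributes, never creates, area
  s_total <- simulate_spectrum(c(GB = 0.004), 0.004, cfg = cfg)
  raw_area <- function(sp) {
    x <- rev(sp$ppm); y <- rev(sp$intensity)
    sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
  }
  expect_equal(raw_area(s_half), raw_area(s_total), tolerance = 1e-4)
})
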