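cfg_q <- spectrum_sim_config() # full resolution for quantification accuracy

test_that("peak detection finds simulated resonances and nothing in a flat spectrum", {
  s <- simulate_spectrum(c(GB = 0.002), standard_conc = 0, cfg = fast_cfg())
  pk <- detect_peaks(s)
  expect_equal(nrow(pk), 2)
  expect_equal(pk$shift, c(3.91, 3.27), tolerance = 1e-3)

  s_std <- simulate_spectrum(c(GB = 0.002), standard_conc = 0.002, cfg = fast_cfg())
  expect_true(any(abs(detect_peaks(s_std)$shift - 0) < 1e-3))

  flat <- nmr_spectrum(seq(10, -0.5, length.out = 1024), rep(0, 1024))
  expect_equal(nrow(detect_peaks(flat)), 0)
})

test_that("peaks in the HOD exclusion window are omitted", {
  lib <- tibble::tibble(solute = "HOD", shift = 4.7, multiplicity = "singlet",
                        j_hz = NA_real_, n_protons = 1L, quant = TRUE,
                        c13_split = FALSE, label = NA_character_)
  s <- simulate_spectrum(c(HOD = 0.01), 0, library = lib, cfg = fast_cfg())
  expect_equal(nrow(detect_peaks(s)), 0)
  expect_equal(nrow(detect_peaks(s, exclusion_windows = list())), 1)
})

test_that("solutes are identified only when all reference peaks match", {
  s <- simulate_spectrum(c(GB = 0.002, Ect = 0.001), 0.002, cfg = cfg_q)
  asn <- assign_solutes(detect_peaks(s))
  id <- unique(asn[, c("solute", "identified")])
  expect_true(id$identified[id$solute == "GB"])
  expect_true(id$identified[id$solute == "Ect"])
  expect_false(id$identified[id$solute == "Ch"])

  s_ect <- simulate_spectrum(c(Ect = 0.001), 0.002, cfg = cfg_q)
  asn2 <- assign_solutes(detect_peaks(s_ect))
  expect_false(any(asn2$identified[asn2$solute == "GB"]))

  # a displaced reference peak beyond 2x tolerance breaks identification
  shifted <- solute_library()
  shifted$shift[shifted$solute == "GB" & shifted$shift == 3.91] <- 3.91 + 0.06
  asn3 <- assign_solutes(detect_peaks(s), shifted, tol = 0.03)
  expect_false(any(asn3$identified[asn3$solute == "GB"]))
})

test_that("assignment is invariant to peak input order", {
  s <- simulate_spectrum(c(GB = 0.002, Ect = 0.001), 0.002, cfg = cfg_q)
  pk <- detect_peaks(s)
  perm <- pk[sample.int(nrow(pk)), ]
  expect_equal(assign_solutes(pk), assign_solutes(perm))
})

test_that("integration captures the expected Lorentzian mass with baseline correction", {
  # unit-area analytic Lorentzian on a fine axis
  fwhm <- 0.00375
  x <- seq(4, 2, length.out = 60000)
  y <- (fwhm / 2 / pi) / ((x - 3)^2 + (fwhm / 2)^2)
  s <- nmr_spectrum(x, y)
  a <- integrate_peak(s, 3, 20 * fwhm)
  # closed form: tail mass inside the window minus the endpoint-baseline trapezoid
  expect_equal(a, lorentz_capture_baseline(20 * fwhm, fwhm), tolerance = 1e-3)
  expect_gt(a, 0.96)
  expect_lte(a, 1.0)

  zero <- nmr_spectrum(x, rep(0, length(x)))
  expect_equal(integrate_peak(zero, 3, 0.05), 0)

  s2 <- nmr_spectrum(x, 2 * y)
  expect_equal(integrate_peak(s2, 3, 20 * fwhm), 2 * a, tolerance = 1e-10)

  expect_error(integrate_peak(s, 3.999, 0.05), "outside")
})

test_that("quantification follows the internal-standard area formula", {
  # A_s/A_std = 0.1 with 9H vs 9H and 500 mM standard -> 50 mM
  s <- simulate_spectrum(c(GB = 0.05), standard_conc = 0.5, cfg = cfg_q)
  q <- quantify(s)
  expect_equal(q$tube_conc_mol_l[q$solute == "GB"], 0.05, tolerance = 0.02)
  expect_equal(q$tube_conc_mol_l[q$solute == "Ect"], 0)
  expect_false(q$identified[q$solute == "Ect"])
})

test_that("quantification round trip recovers generating concentrations", {
  # noise-free: within 2%; 1%-of-max noise: within 10%
  set.seed(11)
  for (i in 1:5) {
    gen <- c(GB = runif(1, 0.01, 0.2), Ect = runif(1, 0.01, 0.2),
             Ch = runif(1, 0.01, 0.2))
    s <- simulate_spectrum(gen, standard_conc = 0.5, cfg = cfg_q)
    q <- quantify(s)
    got <- setNames(q$tube_conc_mol_l, q$solute)[names(gen)]
    expect_equal(unname(got), unname(gen), tolerance = 0.02)
  }
  peak_height <- function(sp) max(sp$intensity)
  s0 <- simulate_spectrum(c(GB = 0.1, Ect = 0.08), standard_conc = 0.5, cfg = cfg_q)
  cfg_n <- spectrum_sim_config(noise_sd = 0.01 * peak_height(s0), seed = 7)
  sn <- simulate_spectrum(c(GB = 0.1, Ect = 0.08), standard_conc = 0.5, cfg = cfg_n)
  qn <- quantify(sn)
  expect_equal(qn$tube_conc_mol_l[qn$solute == "GB"], 0.1, tolerance = 0.1)
  expect_equal(qn$tube_conc_mol_l[qn$solute == "Ect"], 0.08, tolerance = 0.1)
})

test_that("quantification is invariant to rescaling the whole spectrum", {
  s <- simulate_spectrum(c(GB = 0.05), standard_conc = 0.5, cfg = cfg_q)
  s_scaled <- nmr_spectrum(s$ppm, s$intensity * 37.5,
                           spectrometer_freq = spectrometer_freq(s))
  q1 <- quantify(s)
  q2 <- quantify(s_scaled)
  expect_equal(q1$tube_conc_mol_l, q2$tube_conc_mol_l, tolerance = 1e-12)
})

test_that("a missing internal standard is an error, not a silent zero", {
  s <- simulate_spectrum(c(GB = 0.05), standard_conc = 0, cfg = fast_cfg())
  expect_error(quantify(s), "standard")
})

test_that("intracellular scaling is exact and guards its preconditions", {
  # 1 umol in the tube over 1e5 cells of 8.01 pl -> 1.248 mol/l
  tube <- 1e-6 / 600e-6
  expect_equal(intracellular_concentration(tube, 600e-6, 1e5, 8.01),
               1.2484, tolerance = 1e-4)
  expect_equal(intracellular_concentration(0, 1e-3, 10, 8.01), 0)
  base <- intracellular_concentration(0.1, 1e-3, 1e4, 8.01)
  expect_equal(intracellular_concentration(0.1, 1e-3, 2e4, 8.01), base / 2)
  expect_equal(intracellular_concentration(0.2, 1e-3, 1e4, 8.01), base * 2)
  expect_equal(intracellular_concentration(0.1, 2e-3, 1e4, 8.01), base * 2)
  expect_equal(intracellular_concentration(0.1, 1e-3, 1e4, 16.02), base / 2)
  expect_error(intracellular_concentration(0.1, 1e-3, 0, 8.01), "n_cells")
})

test_that("label ratio resolves unlabelled GB, 13C2-GB and Ect", {
  s <- simulate_labeled_spectrum(3e-3, 8e-3, c(Ect = 1e-3), cfg = cfg_q,
                                 standard_conc = 5e-3)
  lr <- label_ratio(s)
  expect_equal(lr$ratio, c(3, 8, 1), tolerance = 0.05)

  s_unl <- simulate_labeled_spectrum(3e-3, 0, c(Ect = 1e-3), cfg = cfg_q,
                                     standard_conc = 5e-3)
  expect_equal(label_ratio(s_unl)$conc_rel[2], 0)

  s_lab <- simulate_labeled_spectrum(0, 3e-3, c(Ect = 1e-3), cfg = cfg_q,
                                     standard_conc = 5e-3)
  lr_lab <- label_ratio(s_lab)
  # central component vanishes up to baseline residue (< 1% of the labelled)
  expect_lt(lr_lab$conc_rel[1], 0.01 * lr_lab$conc_rel[2])
})

test_that("unresolvable satellites raise a diagnostic", {
  s <- simulate_labeled_spectrum(1e-3, 1e-3, cfg = fast_cfg(), standard_conc = 1e-3)
  expect_error(label_ratio(s, j_hz = 2), "overlap")
})
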