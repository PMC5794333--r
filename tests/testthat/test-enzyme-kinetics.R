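test_that("absorbance traces convert to specific activity", {
  tr <- tibble::tibble(time_min = 0:5, absorbance = 1 - 0.0622 * (0:5))
  expect_equal(rates_from_absorbance(tr, protein_mg = 0.001), 10, tolerance = 1e-10)

  flat <- tibble::tibble(time_min = 0:5, absorbance = rep(0.8, 6))
  expect_equal(rates_from_absorbance(flat, protein_mg = 0.001), 0)

  expect_equal(rates_from_absorbance(tr, protein_mg = 0.002), 5, tolerance = 1e-10)

  up <- tibble::tibble(time_min = 0:5, absorbance = 0.1 + 0.01 * (0:5))
  expect_warning(r <- rates_from_absorbance(up, protein_mg = 0.001,
                                            direction = "decrease"),
                 "against")
  expect_gt(r, 0)
})

test_that("noise-free Michaelis-Menten data are recovered to 0.1%", {
  for (p in list(c(0.022, 1486), c(0.68, 1.6))) {
    d <- simulate_rate_data(kinetics_sim_config(p[1], p[2], noise_cv = 0))
    f <- fit_mm(d)
    expect_equal(f$km, p[1], tolerance = 1e-3)
    expect_equal(f$vmax, p[2], tolerance = 1e-3)
    expect_equal(f$specificity_constant, p[2] / p[1], tolerance = 2e-3)
  }
})

test_that("underdetermined or unidentified kinetics are rejected", {
  d2 <- tibble::tibble(substrate_mM = c(1, 1, 2, 2), rate_U_per_mg = c(5, 5.1, 8, 8.2))
  expect_error(fit_mm(d2), "3 distinct substrate levels")
  # rates linear in S far below Km: no plateau information
  dlin <- tibble::tibble(substrate_mM = c(0.001, 0.002, 0.004, 0.008),
                         rate_U_per_mg = c(0.001, 0.002, 0.004, 0.008))
  expect_error(fit_mm(dlin), "Km|converge")
})

test_that("the fit is permutation-invariant and unit-consistent", {
  d <- simulate_rate_data(kinetics_sim_config(0.2, 314, noise_cv = 0.05, seed = 8))
  f1 <- fit_mm(d)
  f2 <- fit_mm(d[sample.int(nrow(d)), ])
  expect_equal(f1$km, f2$km, tolerance = 1e-8)
  expect_equal(f1$vmax, f2$vmax, tolerance = 1e-8)
  # substrate in uM instead of mM rescales Km by 1000, leaves Vmax
  d_um <- dplyr::mutate(d, substrate_mM = substrate_mM * 1000)
  f3 <- fit_mm(d_um)
  expect_equal(f3$km, 1000 * f1$km, tolerance = 1e-6)
  expect_equal(f3$vmax, f1$vmax, tolerance = 1e-6)
})

test_that("tidy and glance expose the fit in broom shape", {
  d <- simulate_rate_data(kinetics_sim_config(0.038, 2062, noise_cv = 0.02, seed = 2),
                          condition = "0.05 M NaCl", enzyme = "MDH")
  f <- fit_mm(d)
  td <- tidy(f)
  expect_equal(td$term, c("Km", "Vmax"))
  expect_true(all(td$std.error > 0))
  gl <- glance(f)
  expect_equal(gl$condition, "0.05 M NaCl")
  expect_equal(gl$specificity_constant, gl$vmax / gl$km)
})

test_that("derived metrics reproduce the published comparison arithmetic", {
  expect_equal(round(specificity_constant(list(km = 0.163, vmax = 227))), 1393)
  expect_equal(round(specificity_constant(list(km = 0.68, vmax = 1.6)), 2), 2.35)
  ref_mdh <- list(km = 0.022, vmax = 1486)
  expect_equal(round(residual_activity(list(km = 0.26, vmax = 78), ref_mdh)), 5)
  expect_equal(residual_activity(ref_mdh, ref_mdh), 100)
  expect_equal(round(residual_activity(list(km = 0.014, vmax = 2.4),
                                       list(km = 0.019, vmax = 6.8))), 35)
  expect_equal(round(osmolyte_performance(list(km = 0.163, vmax = 227), ref_mdh), 1), 2.1)
  expect_equal(osmolyte_performance(ref_mdh, ref_mdh), 100)
  # halving Vmax at fixed Km halves the performance
  expect_equal(osmolyte_performance(list(km = 0.163, vmax = 113.5), ref_mdh),
               osmolyte_performance(list(km = 0.163, vmax = 227), ref_mdh) / 2)
})

test_that("simulated rates honour half-saturation and the asymptote", {
  cfg <- kinetics_sim_config(0.022, 1486, substrate_concs = c(0.022, 220),
                             noise_cv = 0, replicates = 1)
  d <- simulate_rate_data(cfg)
  expect_equal(d$rate_U_per_mg[1], 743, tolerance = 1e-4)
  expect_equal(d$rate_U_per_mg[2], 1486, tolerance = 1e-3)
  # determinism
  cfg_n <- kinetics_sim_config(0.022, 1486, noise_cv = 0.05, seed = 77)
  expect_identical(simulate_rate_data(cfg_n), simulate_rate_data(cfg_n))
})
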