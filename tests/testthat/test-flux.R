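test_that("P_app follows (dQ/dt)/(A C0) with unit conversion", {
  # oracle: hand conversion, Q = 2t nmol/h, A = 1 cm^2, C0 = 0.2 mM
  s <- flux_series(1:4, 2 * (1:4), area_cm2 = 1, C0_mM = 0.2)
  expect_equal(dextran_papp(s)$P_app_cm_s, (2e-9 / 3600) / 2e-7,
               tolerance = 1e-12)
  # constant Q gives zero permeability
  s0 <- flux_series(1:4, rep(5, 4), area_cm2 = 1, C0_mM = 0.2)
  expect_equal(dextran_papp(s0)$P_app_cm_s, 0)
  # single endpoint: slope through the origin
  s1 <- flux_series(1, 2, area_cm2 = 1, C0_mM = 0.2)
  expect_equal(dextran_papp(s1)$P_app_cm_s, (2e-9 / 3600) / 2e-7,
               tolerance = 1e-12)
  # negative slopes warn but return signed
  sn <- flux_series(1:4, c(4, 3, 2, 1), area_cm2 = 1, C0_mM = 0.2)
  expect_warning(out <- dextran_papp(sn), "negative")
  expect_lt(out$P_app_cm_s, 0)
})

test_that("standard curves fit and invert exactly", {
  st <- data.frame(amount_nmol = c(0, 1, 2), fluorescence = c(0, 10, 20))
  cv <- fit_standard_curve(st)
  expect_equal(cv$slope, 10)
  expect_equal(cv$intercept, 0)
  expect_equal(apply_calibration(cv, 15), 1.5)
  expect_equal(apply_calibration(cv, st$fluorescence), st$amount_nmol,
               tolerance = 1e-12)
  expect_error(fit_standard_curve(
    data.frame(amount_nmol = c(1, 1), fluorescence = c(2, 3))), "degenerate")
  expect_error(fit_standard_curve(
    data.frame(amount_nmol = c(0, 1, 2), fluorescence = c(20, 10, 0))),
    "non-positive")
})

test_that("flux series validation enforces ordering and positivity", {
  expect_error(flux_series(c(1, 1, 2), 1:3))
  expect_error(flux_series(1:3, 1:3, C0_mM = 0))
  expect_error(flux_series(c(2, 1), 1:2))
})

test_that("noisy flux estimates stay within a few fitted SEs of truth", {
  fx <- flux_spec(true_P_app = 1e-6, fluorescence_noise_sd = 2, seed = 21)
  res <- analyze_flux(generate_flux_dataset(fx))
  expect_lt(abs(res$P_app_cm_s - 1e-6), 3 * res$se_P_app_cm_s)
})
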