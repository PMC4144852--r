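test_that("TER is blank-subtracted and area-scaled; unphysical records error", {
  r <- electro_record(200, 100, 1, 0, area_cm2 = 1.12)
  expect_equal(compute_ter(r), 112)
  expect_error(compute_ter(electro_record(100, 100, 0, 0)), "unphysical")
  # doubling the area doubles TER
  r2 <- electro_record(200, 100, 1, 0, area_cm2 = 2.24)
  expect_equal(compute_ter(r2), 224)
})

test_that("GHK forward: symmetric permeabilities give 0 mV on the A/B pair", {
  expect_identical(ghk_dilution_potential(1, solution_a(), solution_b()), 0)
  expect_identical(ghk_dilution_potential(3, solution_a(), solution_a()), 0)
})

test_that("GHK forward: Cl-impermeable limit approaches the Nernst value", {
  # closed-form oracle: (RT/F) ln 2 for a 140/70 dilution at 310.15 K
  nernst <- 1000 * 8.314 * 310.15 / 96485 * log(2)
  ap <- ion_solution(Na = 140, K = 0, Cl = 140)
  bl <- ion_solution(Na = 70, K = 0, Cl = 70)
  v <- ghk_dilution_potential(1e9, ap, bl, temperature_K = 310.15)
  expect_equal(v, nernst, tolerance = 1e-6)
  # potential scales with T in this limit
  v2 <- ghk_dilution_potential(1e9, ap, bl, temperature_K = 2 * 310.15)
  expect_equal(v2 / v, 2, tolerance = 1e-6)
})

test_that("GHK forward/inverse round trip over beta in [0.1, 100]", {
  pairs <- list(list(solution_a(), solution_b()),
                list(ion_solution(Na = 120, K = 10, Cl = 135),
                     ion_solution(Na = 45, K = 3, Cl = 60)))
  for (pr in pairs) {
    for (beta in c(0.1, 0.5, 1, 2, 7, 31.6, 100)) {
      v <- ghk_dilution_potential(beta, pr[[1]], pr[[2]])
      bhat <- ghk_ratio(potential_mV = v, apical = pr[[1]],
                        basolateral = pr[[2]])
      expect_equal(bhat, beta, tolerance = 1e-9)
    }
  }
})

test_that("GHK inversion with a decoupled K+ permeability (root finding)", {
  v <- ghk_dilution_potential(7, solution_a(), solution_b(), kappa = 2)
  bhat <- ghk_ratio(potential_mV = v, apical = solution_a(),
                    basolateral = solution_b(), kappa = 2)
  expect_equal(bhat, 7, tolerance = 1e-9)
})

test_that("potentials at or beyond the Nernst limits error with the limits", {
  lim <- epimorph:::ghk_potential_limits(solution_a(), solution_b())
  expect_error(ghk_ratio(potential_mV = lim[2], apical = solution_a(),
                         basolateral = solution_b()), "unbounded")
  expect_error(ghk_ratio(potential_mV = lim[2] + 5, apical = solution_a(),
                         basolateral = solution_b()), "attainable")
})

test_that("Kimizuka-Koketsu: closed-form value and algebraic identities", {
  # independent hand evaluation: P = RT/(F^2 TER C)/2 with
  # R = 8.314, T = 310.15, F = 96485, TER = 50, C = 1.4e-4 mol/cm^3
  hand <- 8.314 * 310.15 / (96485^2 * 50 * 1.4e-4) / 2
  kk <- kimizuka_koketsu(50, 1, reference_NaCl_mM = 140)
  expect_equal(kk$P_Na_cm_s, hand, tolerance = 1e-12)
  expect_equal(kk$P_Na_cm_s, 1.98e-5, tolerance = 0.005)
  for (beta in c(0.2, 1, 7)) {
    kk <- kimizuka_koketsu(123, beta)
    expect_equal(kk$P_Na_cm_s / kk$P_Cl_cm_s, beta, tolerance = 1e-14)
    expect_equal(kk$P_Na_cm_s + kk$P_Cl_cm_s, kk$P_total_cm_s,
                 tolerance = 1e-14)
  }
  a <- kimizuka_koketsu(60, 3)
  b <- kimizuka_koketsu(120, 3)
  expect_equal(a$P_Na_cm_s / b$P_Na_cm_s, 2, tolerance = 1e-12)
})

test_that("noiseless generated records invert to the true permeabilities", {
  es <- electro_spec(true_P_Na = 2.1e-5, true_P_Cl = 3e-6,
                     resistance_noise_sd_ohm = 0, potential_noise_sd_mV = 0,
                     n_replicates = 3)
  res <- analyze_electro(generate_electro_dataset(es))
  expect_equal(res$beta, rep(7, 3), tolerance = 1e-9)
  expect_equal(res$P_Na_cm_s, rep(2.1e-5, 3), tolerance = 1e-9)
  expect_equal(res$P_Cl_cm_s, rep(3e-6, 3), tolerance = 1e-9)
})
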