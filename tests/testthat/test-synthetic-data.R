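test_that("straight mosaics have ground-truth index exactly 1", {
  net <- build_junction_network(tiny_spec(tortuosity_amplitude_um = 0))
  expect_identical(pooled_zigzag_index(net), 1)
  m <- measure_network(net)
  expect_true(all(abs(m$L_TJ_um - m$L_St_um) < 1e-9))
})

test_that("same spec and seed give bit-identical images and truth", {
  sp <- tiny_spec(myosin_mode = "two_row", noise_sd = 2)
  a <- generate_monolayer(sp)
  b <- generate_monolayer(sp)
  expect_identical(a$channels$junction, b$channels$junction)
  expect_identical(a$channels$myosin, b$channels$myosin)
  expect_identical(a$truth$vertices, b$truth$vertices)
  # rendering does not perturb the geometry stream
  expect_identical(build_junction_network(sp)$vertices, a$truth$vertices)
})

test_that("truth network satisfies its structural invariants", {
  sp <- tiny_spec(tortuosity_amplitude_um = 0.4)
  net <- build_junction_network(sp)
  vmap <- stats::setNames(seq_len(nrow(net$vertices)), net$vertices$id)
  for (s in net$sides) {
    p <- s$polyline
    expect_gte(nrow(p), 2L)
    i1 <- vmap[as.character(s$v1)]
    i2 <- vmap[as.character(s$v2)]
    expect_lt(max(abs(p[1, ] - c(net$vertices$x_um[i1], net$vertices$y_um[i1]))), 1e-9)
    expect_lt(max(abs(p[nrow(p), ] - c(net$vertices$x_um[i2], net$vertices$y_um[i2]))), 1e-9)
    expect_gte(polyline_length(p) + 1e-12,
               sqrt(sum((p[nrow(p), ] - p[1, ])^2)))
  }
  # interior vertices of a cell mosaic have degree >= 3
  deg <- integer(nrow(net$vertices))
  names(deg) <- net$vertices$id
  for (s in net$sides) {
    deg[as.character(s$v1)] <- deg[as.character(s$v1)] + 1L
    deg[as.character(s$v2)] <- deg[as.character(s$v2)] + 1L
  }
  onb <- net$vertices$x_um < 1e-6 | net$vertices$y_um < 1e-6 |
    net$vertices$x_um > net$field_um[1] - 1e-6 |
    net$vertices$y_um > net$field_um[2] - 1e-6
  expect_true(all(deg[!onb] >= 3L))
})

test_that("pooled truth index is monotone in amplitude (arc-length oracle)", {
  # independent oracle: arc length accumulated point by point
  arclen <- function(p) {
    tot <- 0
    for (i in 2:nrow(p)) tot <- tot + sqrt(sum((p[i, ] - p[i - 1, ])^2))
    tot
  }
  idx <- vapply(c(0.3, 0.6, 1.0), function(a) {
    net <- build_junction_network(tiny_spec(tortuosity_amplitude_um = a))
    keep <- !vapply(net$sides, `[[`, logical(1), "border")
    ltj <- sum(vapply(net$sides[keep], function(s) arclen(s$polyline), numeric(1)))
    lst <- sum(vapply(net$sides[keep], function(s)
      sqrt(sum((s$polyline[nrow(s$polyline), ] - s$polyline[1, ])^2)), numeric(1)))
    ltj / lst
  }, numeric(1))
  expect_true(all(diff(idx) > 0))
  # and the package's pooled index agrees with the oracle
  expect_equal(pooled_zigzag_index(
    build_junction_network(tiny_spec(tortuosity_amplitude_um = 0.6))),
    idx[2], tolerance = 1e-12)
})

test_that("degenerate tessellations and invalid specs error", {
  expect_error(monolayer_spec(n_cells = 3), "n_cells")
  expect_error(monolayer_spec(pixel_size_um = 0.5, junction_width_um = 0.25),
               "pixel_size_um")
  expect_error(monolayer_spec(tortuosity_amplitude_um = -1))
  expect_error(
    build_junction_network(
      monolayer_spec(field_width_um = 20, field_height_um = 20, n_cells = 5,
                     seed = 2)),
    "degenerate tessellation")
})

test_that("amplitude beyond half the shortest chord records a warning", {
  sp <- tiny_spec(tortuosity_amplitude_um = 4)
  net <- build_junction_network(sp)
  expect_gt(length(attr(net, "warnings")), 0)
  expect_match(attr(net, "warnings")[1], "amplitude")
})

test_that("rendered channels share shape, are non-negative, sized by field", {
  sp <- tiny_spec(myosin_mode = "continuous", noise_sd = 3)
  img <- generate_monolayer(sp)
  expect_equal(dim(img$channels$junction),
               round(c(sp$field_height_um, sp$field_width_um) / sp$pixel_size_um))
  expect_identical(dim(img$channels$junction), dim(img$channels$myosin))
  expect_true(all(img$channels$junction >= 0))
})

test_that("electro generator: forward model inverts exactly without noise", {
  es <- electro_spec(true_P_Na = 1.4e-5, true_P_Cl = 2e-6,
                     resistance_noise_sd_ohm = 0, potential_noise_sd_mV = 0,
                     n_replicates = 2)
  recs <- generate_electro_dataset(es)
  res <- analyze_electro(recs)
  expect_equal(res$P_Na_cm_s, rep(1.4e-5, 2), tolerance = 1e-9)
  expect_equal(res$P_Cl_cm_s, rep(2e-6, 2), tolerance = 1e-9)
})

test_that("electro generator: symmetric permeabilities cancel; replicates reproduce", {
  es <- electro_spec(true_P_Na = 5e-6, true_P_Cl = 5e-6,
                     resistance_noise_sd_ohm = 0, potential_noise_sd_mV = 0,
                     n_replicates = 1)
  r <- generate_electro_dataset(es)[[1]]
  expect_equal(r$raw_potential_mV - r$blank_potential_mV, 0)
  es2 <- electro_spec(n_replicates = 4, seed = 99)
  a <- generate_electro_dataset(es2)
  b <- generate_electro_dataset(es2)
  expect_length(a, 4L)
  expect_identical(vapply(a, `[[`, numeric(1), "raw_resistance_ohm"),
                   vapply(b, `[[`, numeric(1), "raw_resistance_ohm"))
})

test_that("flux generator round-trips and handles zero permeability", {
  fx <- flux_spec(true_P_app = 3.3e-6, fluorescence_noise_sd = 0)
  res <- analyze_flux(generate_flux_dataset(fx))
  expect_equal(res$P_app_cm_s, 3.3e-6, tolerance = 1e-12)
  f0 <- flux_spec(true_P_app = 0, fluorescence_noise_sd = 0)
  ds <- generate_flux_dataset(f0)
  expect_true(all(ds$series$fluorescence == f0$calib_intercept))
})
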