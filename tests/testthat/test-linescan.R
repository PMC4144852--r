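test_that("scans in pure background are flat; zero-length scans error", {
  img <- list(channels = list(junction = matrix(20, 200, 200)),
              pixel_size_um = 0.1)
  sc <- line_scan(img, "junction", c(2, 2), c(15, 9))
  expect_true(all(abs(sc$intensity$junction - 20) < 1e-9))
  expect_error(line_scan(img, "junction", c(2, 2), c(2, 2)), "zero-length")
  expect_error(line_scan(img, "junction", c(-1, 2), c(5, 5)), "inside")
})

test_that("a perpendicular scan across a junction peaks at the crossing", {
  fx <- render_fixture(0)
  m <- measure_network(fx$img$truth)
  ok <- which(!m$border & m$L_St_um > 4)
  s <- fx$img$truth$sides[[match(m$side_id[ok[1]],
    vapply(fx$img$truth$sides, function(x) as.character(x$id), character(1)))]]
  p <- s$polyline
  mid <- (p[1, ] + p[nrow(p), ]) / 2
  u <- (p[nrow(p), ] - p[1, ])
  u <- u / sqrt(sum(u^2))
  nrm <- c(-u[2], u[1])
  sc <- line_scan(fx$img, "junction", mid - 2 * nrm, mid + 2 * nrm,
                  width_um = 0.5)
  peak_pos <- sc$positions_um[which.max(sc$intensity$junction)]
  expect_lt(abs(peak_pos - 2), 0.15)  # within ~1 pixel of the crossing
})

test_that("two-row myosin scans show two peaks ~2 x offset apart", {
  sp <- tiny_spec(tortuosity_amplitude_um = 0, myosin_mode = "two_row",
                  n_cells = 22, seed = 8)
  img <- generate_monolayer(sp)
  m <- measure_network(img$truth)
  ok <- which(!m$border & m$L_St_um > 5)
  s <- img$truth$sides[[match(m$side_id[ok[1]],
    vapply(img$truth$sides, function(x) as.character(x$id), character(1)))]]
  p <- s$polyline
  mid <- (p[1, ] + p[nrow(p), ]) / 2
  u <- (p[nrow(p), ] - p[1, ]) / sqrt(sum((p[nrow(p), ] - p[1, ])^2))
  nrm <- c(-u[2], u[1])
  sc <- line_scan(img, "myosin", mid - 1.5 * nrm, mid + 1.5 * nrm,
                  width_um = 1)
  y <- sc$intensity$myosin
  pk <- sc$positions_um[epimorph:::find_local_maxima(y)[
    order(-y[epimorph:::find_local_maxima(y)])][1:2]]
  expect_equal(abs(diff(sort(pk))), 2 * sp$two_row_offset_um, tolerance = 0.25)
})

test_that("profile classification counts prominent peaks", {
  x <- seq(0, 10, by = 0.05)
  one <- exp(-(x - 5)^2 / 0.5)
  two <- exp(-(x - 3.5)^2 / 0.2) + exp(-(x - 6.5)^2 / 0.2)
  expect_equal(as.character(classify_transverse_profile(one)), "single_peak")
  expect_equal(as.character(classify_transverse_profile(two)), "double_peak")
  expect_equal(as.character(classify_transverse_profile(rep(1, 50))), "none")
  # sub-threshold prominence bumps are ignored
  weak <- one + 0.05 * exp(-(x - 8)^2 / 0.1)
  expect_equal(as.character(classify_transverse_profile(weak, 0.2)),
               "single_peak")
})
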