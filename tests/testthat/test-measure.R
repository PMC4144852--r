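test_that("measure_edge computes path and chord lengths from the polyline", {
  s <- list(id = "a", v1 = 1, v2 = 2, border = FALSE,
            polyline = rbind(c(0, 0), c(3, 4)))
  m <- measure_edge(s)
  expect_equal(m$L_TJ_um, 5)
  expect_equal(m$L_St_um, 5)
  s$polyline <- rbind(c(0, 0), c(1, 1), c(2, 0))
  m <- measure_edge(s)
  expect_equal(m$L_TJ_um, 2 * sqrt(2))
  expect_equal(m$L_St_um, 2)
})

test_that("dense semicircular polyline converges to pi/2", {
  # analytic oracle: half circle of radius 1 over a chord of 2
  th <- seq(pi, 0, length.out = 1e4)
  s <- list(id = 1, v1 = 1, v2 = 2, border = FALSE,
            polyline = cbind(cos(th), sin(th)))
  m <- measure_edge(s)
  expect_equal(m$L_TJ_um / m$L_St_um, pi / 2, tolerance = 1e-4)
})

test_that("coincident vertices are excluded with a message", {
  s <- list(id = "loop", v1 = 1, v2 = 1, border = FALSE,
            polyline = rbind(c(0, 0), c(1, 0), c(0, 0)))
  expect_message(out <- measure_edge(s), "coincident")
  expect_null(out)
})

test_that("zigzag index is the ratio of sums, not the mean of ratios", {
  m <- data.frame(side_id = c("a", "b"), L_TJ_um = c(3, 5),
                  L_St_um = c(2, 4), border = FALSE,
                  stringsAsFactors = FALSE)
  z <- compute_zigzag_index(c("a", "b"), m)
  expect_equal(z$value, 8 / 6)
  expect_equal(z$n_sides, 2L)
  # permutation invariance, bit-identical
  expect_identical(z$value, compute_zigzag_index(c("b", "a"), m)$value)
  expect_error(compute_zigzag_index(character(0), m), "empty side set")
  expect_error(compute_zigzag_index("zzz", m), "unknown side")
})

test_that("clone summary aggregates windows -> samples -> mean +/- SE", {
  one <- clone_zigzag_summary(list(c(1.2, 1.4)))
  expect_equal(one$sample_means, 1.3)
  expect_true(is.na(one$se))
  expect_equal(one$n, 1L)
  three <- clone_zigzag_summary(list(1.2, 1.3, 1.4))
  expect_equal(three$mean, 1.3)
  expect_equal(three$se, 0.1 / sqrt(3))
  expect_equal(three$n, 3L)
})
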