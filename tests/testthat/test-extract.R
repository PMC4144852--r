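test_that("a single straight 1-px line yields one side with L_TJ = L_St", {
  mask <- matrix(FALSE, 40, 60)
  mask[20, 10:50] <- TRUE
  net <- extract_network(mask, pixel_size_um = 0.1, prune_spur_um = 0)
  expect_length(net$sides, 1L)
  expect_equal(nrow(net$vertices), 2L)
  m <- measure_network(net)
  expect_equal(m$L_TJ_um, m$L_St_um, tolerance = 1e-9)
  expect_equal(m$L_St_um, 4.0, tolerance = 1e-9)
})

test_that("a plus-sign mask forces one degree-4 vertex and four sides", {
  mask <- matrix(FALSE, 41, 41)
  mask[21, 5:37] <- TRUE
  mask[5:37, 21] <- TRUE
  net <- extract_network(mask, pixel_size_um = 0.1, prune_spur_um = 0,
                         border_margin_px = 0)
  expect_length(net$sides, 4L)
  deg <- table(unlist(lapply(net$sides, function(s) c(s$v1, s$v2))))
  expect_equal(sort(as.integer(deg)), c(1L, 1L, 1L, 1L, 4L))
})

test_that("empty masks error", {
  expect_error(extract_network(matrix(FALSE, 10, 10), 0.1), "empty")
})

test_that("noiseless straight render reproduces truth topology and length", {
  fx <- render_fixture(0)
  mt <- measure_network(fx$img$truth)
  mp <- measure_network(fx$net)
  expect_equal(sum(!mp$border), sum(!mt$border))
  expect_lt(abs(sum(mp$L_TJ_um[!mp$border]) - sum(mt$L_TJ_um[!mt$border])) /
              sum(mt$L_TJ_um[!mt$border]), 0.02)
})

test_that("pipeline index tracks truth within 5% and preserves ordering", {
  amps <- c(0, 0.35, 0.56)
  truth <- numeric(3)
  pipe <- numeric(3)
  for (i in seq_along(amps)) {
    fx <- render_fixture(amps[i])
    truth[i] <- pooled_zigzag_index(fx$img$truth)
    pipe[i] <- pooled_zigzag_index(fx$net)
  }
  expect_true(all(abs(pipe - truth) / truth <= 0.05))
  expect_true(all(diff(pipe) > 0))
})

test_that("rotating the image by 90 degrees changes the index by < 1%", {
  fx <- render_fixture(0.35)
  base <- pooled_zigzag_index(fx$net)
  rotch <- t(fx$img$channels$junction)[, nrow(fx$img$channels$junction):1]
  rimg <- list(channels = list(junction = rotch),
               pixel_size_um = fx$img$pixel_size_um)
  rmask <- segment_junctions(rimg)
  rnet <- suppressMessages(extract_network(rmask, rimg$pixel_size_um))
  expect_lt(abs(pooled_zigzag_index(rnet) - base) / base, 0.01)
})
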