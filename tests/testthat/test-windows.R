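test_that("a window covering the whole field captures every eligible side", {
  net <- build_junction_network(tiny_spec())
  w <- sample_windows(net, window_area_um2 = 40 * 40, n_windows = 1, seed = 1)
  elig <- vapply(net$sides, function(s) !isTRUE(s$border) && s$v1 != s$v2,
                 logical(1))
  expect_setequal(w[[1]]$side_ids,
                  vapply(net$sides[elig], function(s) as.character(s$id),
                         character(1)))
})

test_that("window placement is seed-deterministic", {
  net <- build_junction_network(tiny_spec())
  a <- sample_windows(net, n_windows = 5, seed = 42)
  b <- sample_windows(net, n_windows = 5, seed = 42)
  expect_identical(a, b)
  c2 <- sample_windows(net, n_windows = 5, seed = 43)
  expect_false(identical(a, c2))
})

test_that("default dense mosaic pools >= 80 sides over five standard windows", {
  net <- cached("default_truth_net",
                build_junction_network(monolayer_spec(seed = 3)))
  wz <- window_zigzag(net, window_area_um2 = 840, n_windows = 5, seed = 3)
  expect_gte(wz$n_sides_total, 80)
  expect_true(all(wz$indices >= 1))
})

test_that("window membership requires both vertices inside", {
  net <- build_junction_network(tiny_spec())
  vx <- stats::setNames(net$vertices$x_um, net$vertices$id)
  vy <- stats::setNames(net$vertices$y_um, net$vertices$id)
  w <- sample_windows(net, window_area_um2 = 100, n_windows = 3, seed = 9)
  for (win in w) {
    for (sid in win$side_ids) {
      s <- net$sides[[match(sid, vapply(net$sides, function(x)
        as.character(x$id), character(1)))]]
      for (v in c(s$v1, s$v2)) {
        expect_gte(vx[as.character(v)], win$x0_um)
        expect_lte(vx[as.character(v)], win$x0_um + win$size_um)
        expect_gte(vy[as.character(v)], win$y0_um)
        expect_lte(vy[as.character(v)], win$y0_um + win$size_um)
      }
    }
  }
})

test_that("oversized windows and fieldless networks error", {
  net <- build_junction_network(tiny_spec())
  expect_error(sample_windows(net, window_area_um2 = 100 * 100), "exceeds")
})
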