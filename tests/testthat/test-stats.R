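test_that("identical groups give t = 0, p = 1", {
  z <- students_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(z$t, 0)
  expect_equal(z$p, 1)
  expect_false(z$significant)
  expect_equal(z$df, 4)
})

test_that("pooled test matches stats::t.test(var.equal = TRUE) on random data", {
  withr::with_seed(17, {
    for (i in 1:50) {
      a <- rnorm(sample(3:9, 1), mean = runif(1, -2, 2), sd = runif(1, 0.2, 3))
      b <- rnorm(sample(3:9, 1), mean = runif(1, -2, 2), sd = runif(1, 0.2, 3))
      ours <- students_t_test(a, b)
      ref <- stats::t.test(a, b, var.equal = TRUE)
      expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-10)
      expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
      expect_equal(ours$df, unname(ref$parameter))
    }
  })
})

test_that("Welch option matches stats::t.test default", {
  withr::with_seed(18, {
    a <- rnorm(6, 0, 1)
    b <- rnorm(9, 1, 3)
    ours <- students_t_test(a, b, var_equal = FALSE)
    ref <- stats::t.test(a, b)
    expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
    expect_equal(ours$df, unname(ref$parameter), tolerance = 1e-10)
  })
})

test_that("degenerate zero-variance cases follow the stated conventions", {
  z <- students_t_test(c(2, 2, 2), c(2, 2))
  expect_equal(z$p, 1)
  expect_error(students_t_test(c(1, 1, 1), c(2, 2, 2)), "degenerate")
  expect_error(students_t_test(1, c(1, 2)))
})
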