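test_that("ion totals follow the salt recipes, divalent Cl counted twice", {
  a <- solution_a()
  expect_equal(a$Na, 140)
  expect_equal(a$K, 5)
  expect_equal(a$Cl, 140 + 5 + 2 * 1 + 2 * 1)
  b <- solution_b()
  expect_equal(b$Na, 70)
  expect_equal(b$Cl, 70 + 5 + 2 + 2)
  s <- ion_solution(NaCl = 10, KCl = 2, MgCl2 = 3, CaCl2 = 4)
  expect_equal(s$Cl, 10 + 2 + 6 + 8)
})

test_that("explicit totals bypass the recipe and partial totals error", {
  s <- ion_solution(Na = 1, K = 2, Cl = 3)
  expect_equal(unlist(s[c("Na", "K", "Cl")]), c(Na = 1, K = 2, Cl = 3))
  expect_error(ion_solution(Na = 1), "all of Na, K and Cl")
  expect_error(ion_solution(NaCl = -1))
})
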