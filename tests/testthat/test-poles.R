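test_that("K = 0 poles are -l(l+1) with all residue in the lead", {
  fp <- find_poles(0, 4)
  expect_equal(Re(fp$poles), c(0, -2, -6, -12), tolerance = 1e-10)
  expect_equal(Re(fp$residues[1]), 1, tolerance = 1e-10)
  expect_lt(max(Mod(fp$residues[-1])), 1e-10)
})

test_that("the leading pole is a zero of the inverse fraction", {
  fp <- find_poles(0.5, 2)
  expect_gt(Mod(continued_fraction(0.5, fp$poles[1] + 1e-6)), 1e4)
})

test_that("pole expansion reproduces the rigid-rod factor at tiny N", {
  # N -> 0: G(K;N) -> sin(KN)/(KN)
  for (K in c(1, 2, 5)) {
    fp <- find_poles(K, 40)
    s <- Re(sum(fp$residues * exp(fp$poles * 1e-3)))
    expect_equal(s, sin(K * 1e-3) / (K * 1e-3), tolerance = 1e-4)
  }
})

test_that("poles come in conjugate pairs once collisions have occurred", {
  fp <- find_poles(20, 8)
  im <- Im(fp$poles)
  expect_true(any(abs(im) > 1))
  expect_equal(sort(im), sort(-im), tolerance = 1e-6)
})

test_that("near-degenerate pairs raise the collision flag", {
  fp0 <- find_poles(0.5, 3)
  expect_false(fp0$collision)
  expect_true(find_poles(0.5, 3, tol = 10)$collision)
})
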