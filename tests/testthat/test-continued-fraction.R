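test_that("continued fraction reduces to 1/p at K = 0", {
  for (p in c(0.5, 2, 7 + 3i))
    expect_equal(continued_fraction(0, p), as.complex(1 / p), tolerance = 1e-14)
})

test_that("shallow truncation matches the hand-evaluated fraction", {
  # l_max = 2: 1/(1 + (1/3)/(3 + (4/15)/7)) with a1^2 = 1/3, a2^2 = 4/15
  hand <- 1 / (1 + (1 / 3) / (3 + (4 / 15) / 7))
  expect_equal(Re(continued_fraction(1, 1, l_max = 2)), hand, tolerance = 1e-12)
  expect_equal(hand, 0.9011299435, tolerance = 1e-9)
})

test_that("large p recovers the leading 1/p behaviour", {
  for (p in c(1e4, 1e6))
    expect_equal(Re(continued_fraction(3, p)) * p, 1, tolerance = 1e-3)
})

test_that("adaptive truncation is stable against further deepening", {
  for (K in c(2, 37, 410)) {
    g1 <- continued_fraction(K, 1.5 + 0.7i)
    g2 <- continued_fraction(K, 1.5 + 0.7i,
                             l_max = 2 * wlcbuckle:::.cf_lmax(K) + 5)
    expect_lt(Mod(g1 - g2) / Mod(g2), 1e-11)
  }
})
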