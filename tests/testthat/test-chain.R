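test_that("chain_spec enforces the dimensionless reductions", {
  ch <- chain_spec(L = 25, lp = 50)
  expect_equal(ch$N, 0.25)
  expect_equal(ch$kappa, 50)
  ch2 <- chain_spec(N = 1)
  expect_equal(ch2$L / (2 * ch2$lp), 1)
  expect_error(chain_spec(L = -1, lp = 50))
  expect_error(chain_spec())
})

test_that("unit conversions are exact and invert", {
  ch <- chain_spec(L = 25, lp = 50, kBT = 4.1)   # kBT in pN nm
  expect_equal(unit_convert(25, "nm", "2lp", ch), 0.25)
  expect_equal(unit_convert(1, "kBT/2lp", "pN", ch), 0.041)
  x <- 3.7
  for (u in list(c("nm", "2lp"), c("pN", "kBT/2lp"), c("J", "kBT")))
    expect_equal(unit_convert(unit_convert(x, u[1], u[2], ch), u[2], u[1], ch), x)
  expect_error(unit_convert(1, "nm", "pN", ch))
})
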