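test_that("G(K;N) satisfies normalization and rigid-rod limits", {
  expect_equal(greens_K_N(0, 1), 1, tolerance = 1e-12)
  expect_equal(greens_K_N(0, 0.25), 1, tolerance = 1e-12)
  expect_equal(greens_K_N(2, 1e-3), sin(2e-3) / 2e-3, tolerance = 1e-4)
  for (K in c(0.5, 2, 4.9))   # K*N <= 5
    expect_equal(greens_K_N(K, 1e-3), sin(K * 1e-3) / (K * 1e-3),
                 tolerance = 1e-4)
})

test_that("small-K expansion recovers the closed-form second moment", {
  # <r^2> = 6 (1 - G(K;N))/K^2 as K -> 0
  for (N in c(0.25, 1)) {
    K <- 1e-3
    expect_equal((1 - greens_K_N(K, N)) * 6 / K^2, mean_square_r(N),
                 tolerance = 1e-5)
  }
  expect_equal(mean_square_r(1), 1 - (1 - exp(-2)) / 2)
  expect_equal(mean_square_r(0.25), 0.25 - (1 - exp(-0.5)) / 2)
  # rod limit: <r^2> -> N^2
  expect_equal(mean_square_r(1e-4) / 1e-8, 1, tolerance = 1e-3)
})

test_that("residue and contour inversions agree where the contour is certified", {
  n_cert <- 0
  for (N in c(0.25, 1)) for (K in c(0.5, 5, 12, 20)) {
    a <- greens_K_N(K, N)
    b <- greens_K_N(K, N, method = "contour")
    if (attr(b, "precision") < 1e-8 * abs(a)) {
      expect_lt(abs(a - b) / abs(a), 1e-8)
      n_cert <- n_cert + 1
    }
  }
  expect_gte(n_cert, 6)
})

test_that("radial distribution passes normalization and moment oracles", {
  for (N in c(0.5, 1, 2)) {
    g <- greens_r_N(N)
    expect_lt(abs(g$norm_check - 1), 1e-3)
    expect_lt(abs(g$moment_check / mean_square_r(N) - 1), 1e-3)
    expect_true(all(g$r2G >= 0))
    # support contract: the radial density vanishes towards full extension
    expect_lt(tail(g$r2G, 1), 1e-4 * max(g$r2G))
  }
})

test_that("a long chain approaches the Gaussian radial density", {
  # the finite-length correction to the Gaussian limit decays like 1/N
  # and is still ~23% of the peak at N = 4, ~9% at N = 8
  devs <- vapply(c(4, 8), function(N) {
    g <- greens_r_N(N)
    s2 <- mean_square_r(N)
    gauss <- 4 * pi * g$r^2 * exp(-1.5 * g$r^2 / s2) * (1.5 / (pi * s2))^1.5
    max(abs(g$r2G - gauss)) / max(g$r2G)
  }, numeric(1))
  expect_lt(devs[1], 0.3)
  expect_lt(devs[2], 0.12)
  expect_lt(devs[2], devs[1])   # and it shrinks with N
})

test_that("free-energy grid is denser near full extension and interior", {
  g <- greens_r_N(1)
  expect_true(all(g$r > 0 & g$r < 1))
  dr <- diff(g$r)
  expect_lt(tail(dr, 1), head(dr, 1))
})
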