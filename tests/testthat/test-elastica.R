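test_that("Euler force follows the hinged-rod formula", {
  expect_equal(euler_force(1), pi^2 / 2)
  ch <- chain_spec(L = 50, lp = 50)
  expect_equal(euler_force(ch), 50 * pi^2 / 2500)
  # doubling L quarters fE
  expect_equal(euler_force(chain_spec(L = 100, lp = 50)) /
               euler_force(chain_spec(L = 50, lp = 50)), 0.25)
})

test_that("extension is exactly 1 below the Euler force and continuous at it", {
  N <- 0.25
  fE <- euler_force(N)
  expect_identical(elastica_extension(N, 0.5 * fE), 1)
  expect_identical(elastica_extension(N, -2), 1)
  expect_identical(elastica_extension(N, fE), 1)
  expect_equal(elastica_extension(N, fE * (1 + 1e-8)), 1, tolerance = 1e-4)
  expect_lt(elastica_extension(N, 2 * fE), 1)
})

test_that("elliptic solution matches the discrete-segment minimizer", {
  N <- 0.25
  fE <- euler_force(N)
  for (fr in c(1.05, 2, 4)) {
    e_ell <- elastica_extension(N, fr * fE)
    d <- elastica_discrete(N, fr * fE)
    expect_lt(abs(e_ell - d$extension) / max(abs(e_ell), 1e-3), 1e-3)
  }
})

test_that("constrained bending energy behaves at and near full extension", {
  N <- 0.25
  sol <- min_bend_energy_at_R(N, N)
  expect_equal(sol$bend_energy, 0)
  expect_true(all(sol$theta == 0))
  # small-retraction energetics: E ~ fE (L - R)
  R <- 0.99 * N
  eb <- min_bend_energy_at_R(N, R)$bend_energy
  expect_lt(abs(eb / (euler_force(N) * (N - R)) - 1), 0.02)
  # monotone growth with retraction
  ebs <- vapply(c(0.9, 0.7, 0.5, 0.3) * N,
                function(r) min_bend_energy_at_R(N, r)$bend_energy, numeric(1))
  expect_true(all(diff(ebs) > 0))
  expect_error(min_bend_energy_at_R(N, -0.1))
})

test_that("constrained elliptic energy matches the penalty minimizer", {
  N <- 0.25
  for (RL in c(0.9, 0.5)) {
    e_ell <- min_bend_energy_at_R(N, RL * N)$bend_energy
    e_dis <- elastica_discrete_R(N, RL * N)$bend_energy
    expect_lt(abs(e_ell / e_dis - 1), 1e-3)
  }
})

test_that("force and constrained energy form a Legendre pair", {
  # d(E_bend)/d(L-R) equals the conjugate force of the buckled branch
  N <- 0.5
  RL <- seq(0.45, 0.9, length.out = 20)
  for (x in RL[c(3, 10, 17)]) {
    h <- 1e-5 * N
    dE <- (min_bend_energy_at_R(N, x * N - h)$bend_energy -
           min_bend_energy_at_R(N, x * N + h)$bend_energy) / (2 * h)
    f <- min_bend_energy_at_R(N, x * N)$f
    expect_lt(abs(dE / f - 1), 1e-2)
  }
})
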