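test_that("build_chain places beads on an exact arc", {
  ch <- build_chain(0.25, 51, R_init = 0.125)
  ed <- sqrt(sum((ch$positions[, 51] - ch$positions[, 1])^2))
  expect_lt(abs(ed - 0.125), 1e-12)
  bonds <- sqrt(colSums((ch$positions[, -1] - ch$positions[, -51])^2))
  expect_lt(max(abs(bonds - ch$ds)), 1e-14)
  expect_equal(ch$ds, 0.005)
  expect_equal(ch$k_bend, 100)
  # straight chain
  chs <- build_chain(0.25, 51)
  expect_equal(bending_energy(chs), 0)
  expect_error(build_chain(0.25, 51, R_init = 0.3))
  expect_error(build_chain(0.25, 4))
})

test_that("bending energy matches single-joint and continuum limits", {
  # one joint bent by theta: k (1 - cos theta)
  ch <- build_chain(1, 5)
  p <- ch$positions
  th <- 0.4
  p[, 4:5] <- {
    rot <- matrix(c(cos(th), 0, -sin(th), 0, 1, 0, sin(th), 0, cos(th)), 3)
    sweep(rot %*% sweep(p[, 4:5], 1, p[, 3]), 1, p[, 3], "+")
  }
  ch$positions <- p
  expect_equal(bending_energy(ch), ch$k_bend * (1 - cos(th)), tolerance = 1e-10)
  # semicircular arc: all joints share the bend angle beta solving the
  # discrete chord relation, so E = k (Nb-2)(1 - cos beta); re-derive beta
  # independently here
  for (Nb in c(51, 201)) {
    arc <- build_chain(0.25, Nb, R_init = 0.25 * 2 / pi)
    k <- arc$k_bend
    q <- (0.25 * 2 / pi) / arc$ds
    beta <- uniroot(function(b) sin((Nb - 1) * b / 2) / sin(b / 2) - q,
                    c(1e-9, 2 * pi / (Nb - 1) - 1e-9), tol = 1e-14)$root
    expect_equal(bending_energy(arc), k * (Nb - 2) * (1 - cos(beta)),
                 tolerance = 1e-8)
  }
  expect_lt(abs(bending_energy(build_chain(0.25, 201, R_init = 0.25 * 2 / pi)) /
                (pi^2 / (4 * 0.25)) - 1), 0.01)
})

test_that("runs are reproducible and conserve the fixed extension exactly", {
  ch <- build_chain(0.25, 31, R_init = 0.2)
  cfg <- list(n_sweeps = 2e4, n_equil = 5e3)
  r1 <- mc_fixed_R(ch, seed = 7, config = cfg)
  r2 <- mc_fixed_R(ch, seed = 7, config = cfg)
  expect_identical(r1$Epoly_samples, r2$Epoly_samples)
  expect_lt(r1$max_R_violation, 1e-10 * 0.25)
  expect_true(r1$acceptance_rate > 0 && r1$acceptance_rate < 1)
  expect_error(mc_fixed_R(build_chain(0.25, 31)))
})

test_that("free-chain energy matches the independent-joint closed form", {
  ch <- build_chain(0.25, 11)
  run <- mc_fixed_f(ch, f = 0, seed = 3,
                    config = list(n_sweeps = 1e5, n_equil = 1e4))
  expect_lt(abs(run$Epoly_mean - free_chain_energy(11, ch$k_bend)),
            3 * run$Epoly_sem)
  # and the end-to-end moment matches the exact discrete closed form
  m2 <- mean(run$R_samples^2)
  m2_se <- sd(run$R_samples^2) / sqrt(length(run$R_samples) / 20)
  expect_lt(abs(m2 - discrete_mean_square_R(11, ch$ds, ch$k_bend)), 3 * m2_se)
})

test_that("compression beyond the Euler force retracts the ends strongly", {
  fE <- euler_force(0.25)
  r1 <- mc_fixed_f(build_chain(0.25, 21), f = 0.67 * fE, seed = 5,
                   config = list(n_sweeps = 5e4, n_equil = 1e4))
  r2 <- mc_fixed_f(build_chain(0.25, 21), f = 2 * fE, seed = 5,
                   config = list(n_sweeps = 5e4, n_equil = 1e4))
  expect_lt(mean(r2$R_samples), 0.6 * mean(r1$R_samples))
})

test_that("crankshaft sampling matches rejection sampling for free joints", {
  # k_bend = 0 (freely jointed), Nb = 7, fixed ends: compare the mean
  # squared distance of an interior bead from the first bead against a
  # direct-rejection sample of free chains with matching end distance
  set.seed(42)
  Nb <- 7; N <- 0.3; Rt <- 0.15
  ds <- N / (Nb - 1)
  nrej <- 2e5
  u <- matrix(rnorm(3 * (Nb - 1) * nrej), nrow = 3)
  u <- sweep(u, 2, sqrt(colSums(u^2)), "/") * ds
  stat <- numeric(0)
  for (i in seq_len(nrej)) {
    b <- u[, ((i - 1) * (Nb - 1) + 1):(i * (Nb - 1))]
    p <- rbind(c(0, 0, 0), apply(b, 1, cumsum))   # Nb x 3 bead positions
    ed <- sqrt(sum(p[Nb, ]^2))
    if (abs(ed - Rt) < 0.02 * N)
      stat <- c(stat, sum(p[4, ]^2))
  }
  run <- mc_fixed_R(build_chain(N, Nb, R_init = Rt), seed = 9, k_bend = 0,
                    config = list(n_sweeps = 2e5, n_equil = 2e4,
                                  n_snapshots = 5000))
  mc_stat <- vapply(seq_len(ncol(run$snapshots)), function(j) {
    p <- matrix(run$snapshots[, j], nrow = 3)
    sum((p[, 4] - p[, 1])^2)
  }, numeric(1))
  se <- sqrt(sd(stat)^2 / length(stat) + sd(mc_stat)^2 / (length(mc_stat) / 10))
  expect_lt(abs(mean(stat) - mean(mc_stat)), 3 * se)
})

test_that("reference energy follows the published convention and regression", {
  expect_equal(reference_energy(51), 117.5)
  expect_equal(reference_energy(4), 0)
  fits <- data.frame(Nb = c(11, 31, 51), Epoly_mean = c(11, 31.2, 50.8))
  em <- reference_energy(51, "empirical", fits = fits)
  expect_equal(em$slope, 0.995, tolerance = 1e-2)
  expect_error(reference_energy(51, "empirical", fits = fits[1:2, ]))
})

test_that("entropy decomposition is an exact identity", {
  d <- entropy_decomposition(10, 4, 6)
  expect_equal(d$TS, 0)
  d2 <- entropy_decomposition(59.3, 54.1, 3.7)
  expect_equal(d2$check, 0)
  expect_equal(d2$TS + d2$F, d2$Epoly_minus_E0)
})

test_that("empirical histogram integrates to one", {
  set.seed(1)
  x <- abs(rnorm(2e4, 0.2, 0.02))
  eg <- empirical_green(x, n_bins = 20)
  expect_equal(sum(eg$density * diff(range(x)) / 20), 1, tolerance = 1e-6)
  expect_warning(empirical_green(x[1:100]))
})
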