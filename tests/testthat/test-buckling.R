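test_that("minimize_profile finds the vertex of a convex toy profile", {
  r <- seq(0.01, 0.99, length.out = 201)
  mn <- minimize_profile(list(r = r, F_values = (r - 0.2)^2))
  expect_equal(mn$Rmin, 0.2, tolerance = 1e-6)
  expect_false(mn$boundary)
  # boundary minimum is flagged
  mn2 <- minimize_profile(list(r = r, F_values = r))
  expect_true(mn2$boundary)
})

test_that("profiles at two forces differ exactly by (f2 - f1) r", {
  g <- greens_r_N(0.5)
  p0 <- free_energy_profile(0.5, 0, green = g)
  p1 <- free_energy_profile(0.5, 3, green = g)
  fin <- is.finite(p0$F_values)
  expect_equal(p1$F_values[fin] - p0$F_values[fin], 3 * p0$r[fin])
  expect_equal(p1$Ef_values, 3 * p1$r)
})

test_that("zero-force minimum matches a dense brute-force scan of r^2 G", {
  g <- greens_r_N(1)
  mn <- minimize_profile(free_energy_profile(1, 0, green = g))
  fin <- is.finite(g$F0)
  sp <- splinefun(g$r[fin], g$F0[fin], method = "natural")
  rr <- seq(min(g$r[fin]), max(g$r[fin]), length.out = 2000)
  expect_lt(abs(mn$Rmin - rr[which.min(sp(rr))]), 2 * max(diff(g$r)))
})

test_that("a short stiff chain is nearly fully extended at zero force", {
  g <- greens_r_N(0.25)
  mn <- minimize_profile(free_energy_profile(0.25, 0, green = g))
  expect_gt(mn$Rmin / 0.25, 0.9)
  # weak compression barely moves the minimum (strong pre-buckling
  # resistance): f/fE = 0.67 shifts Rmin by < 5% of L
  fE <- euler_force(0.25)
  mn2 <- minimize_profile(free_energy_profile(0.25, 0.67 * fE, green = g))
  expect_lt(abs(mn2$Rmin - mn$Rmin) / 0.25, 0.05)
})

test_that("force-extension curve is monotone with a stabilized critical force", {
  g <- greens_r_N(0.5)
  fx <- force_extension(0.5, green = g)
  expect_true(all(diff(fx$Rmin) < 1e-9))
  # tension extends the chain beyond its zero-force extension
  i0 <- which.min(abs(fx$f_grid))
  expect_gt(fx$Rmin[1], fx$Rmin[i0])
  # fluctuations elevate the critical force above the Euler force
  expect_gt(fx$fc_over_fE, 1)
  expect_equal(fx$fE, euler_force(0.5))
  # smoothness: no jump exceeding a few grid steps of the transition slope
  expect_lt(max(abs(diff(fx$Rmin_over_L))), 0.15)
})

test_that("thermodynamic consistency: envelope theorem at the minimum", {
  g <- greens_r_N(0.5)
  fE <- euler_force(0.5)
  fin <- is.finite(g$F0)
  sp <- splinefun(g$r[fin], g$F0[fin], method = "natural")
  for (f in c(0.5, 1.5) * fE) {
    mn <- minimize_profile(free_energy_profile(0.5, f, green = g))
    h <- 1e-4 * fE
    mnp <- minimize_profile(free_energy_profile(0.5, f + h, green = g))
    mnm <- minimize_profile(free_energy_profile(0.5, f - h, green = g))
    dFdf <- (mnp$F_min - mnm$F_min) / (2 * h)
    expect_lt(abs(dFdf / mn$Rmin - 1), 1e-2)
  }
})

test_that("stiff chains converge to the zero-temperature elastica curve", {
  # sup-norm gap between Rmin/L(f/fE) and the elastica shrinks with N
  gaps <- vapply(c(0.5, 0.25, 0.1), function(N) {
    fx <- suppressWarnings(force_extension(N))
    keep <- !fx$pinned
    ela <- elastica_extension(N, fx$f_grid[keep])
    max(abs(fx$Rmin_over_L[keep] - ela))
  }, numeric(1))
  expect_true(all(diff(gaps) < 0))
})

test_that("critical-force surface assembles and reports the Euler column", {
  cs <- critical_force_surface(c(0.5, 1))
  expect_equal(cs$table$fE, pi^2 / (2 * c(0.5, 1)^2))
  expect_true(all(cs$table$fc_over_fE > 1))
  expect_true(all(cs$surface$Rmin_over_L > 0 & cs$surface$Rmin_over_L <= 1))
})
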