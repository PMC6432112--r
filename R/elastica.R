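# Zero-temperature reference: Euler buckling of a hinged elastic rod.
#
# The first buckling mode of a hinged-hinged rod under compressive load f
# is the classical elastica, solved by the pendulum equation. With elliptic
# modulus m = sin^2(alpha/2) (alpha the end tangent angle), the standard
# parametric solution is
#   sqrt(f/kappa) * L = 2 K(m),   R/L = 2 E(m)/K(m) - 1,
# and the bending energy of the constrained shape has the closed form
#   E_bend = (8 kappa / L) (K E - K^2 + m K^2).
# Below the Euler force fE = pi^2 kappa / L^2 the straight rod is the
# minimizer (extension 1, zero bending energy); the transition at fE is
# second order.

#' Euler buckling force of a hinged rod
#'
#' Returns `fE = kBT * lp * pi^2 / L^2`, the critical compressive load of a
#' hinged-hinged elastic rod. In internal units (force in `kBT/(2lp)`,
#' `N = L/(2lp)`) this is `pi^2/(2 N^2)`.
#'
#' @param chain a [chain_spec()] or a dimensionless length `N`.
#' @return the Euler force (units `kBT/(2lp)` when a bare `N` is given,
#'   otherwise `kBT`-energy per `chain` length unit).
#' @examples
#' euler_force(1)                      # pi^2/2
#' euler_force(chain_spec(L = 50, lp = 50))
#' @export
euler_force <- function(chain) {
  if (inherits(chain, "chain_spec"))
    chain$kBT * chain$lp * pi^2 / chain$L^2
  else {
    N <- .as_N(chain)
    pi^2 / (2 * N^2)
  }
}

# solve the elliptic modulus m from K(m) = target (monotone increasing,
# K(0) = pi/2, K(m) -> Inf as m -> 1)
.solve_m_from_K <- function(Ktarget) {
  if (Ktarget <= pi / 2) return(0)
  uniroot(function(m) pracma::ellipke(m)$k - Ktarget,
          lower = 1e-14, upper = 1 - 1e-14, tol = 1e-14)$root
}

#' Force-extension of the buckled elastica
#'
#' End extension `R/L` of a hinged-hinged elastic rod under compressive
#' force `f` at zero temperature. For `f <= fE` the rod is straight
#' (`R/L = 1`); beyond the Euler force the buckled-branch extension follows
#' the parametric elliptic-integral solution, continuous at `fE`
#' (second-order transition).
#'
#' @param chain a [chain_spec()] or dimensionless length `N`.
#' @param f compressive force (same units as [euler_force()] for the given
#'   `chain`); negative values mean tension and return 1 (the straight rod
#'   remains the zero-temperature minimizer under tension).
#' @return extension `R/L` in `[-1, 1]`.
#' @examples
#' N <- 0.25
#' elastica_extension(N, 0.5 * euler_force(N))   # 1
#' elastica_extension(N, 2 * euler_force(N))     # buckled, < 1
#' @export
elastica_extension <- function(chain, f) {
  fE <- euler_force(chain)
  vapply(f, function(fi) {
    if (fi <= fE) return(1)
    # K(m) = (L/2) sqrt(f/kappa); in any units f/fE = (2K/pi)^2
    Ktarget <- (pi / 2) * sqrt(fi / fE)
    m <- .solve_m_from_K(Ktarget)
    ke <- pracma::ellipke(m)
    ext <- 2 * ke$e / ke$k - 1
    if (ext < -1 + 1e-9)
      stop("force so large that the elastica self-contacts (R/L <= -1)")
    ext
  }, numeric(1))
}

#' Minimal bending energy of an elastica at fixed end-to-end distance
#'
#' The hinged-end planar elastica shape minimizing the bending energy
#' subject to end-to-end distance `R`, via the same elliptic
#' parameterization with `R` as the control variable. The bending energy is
#' zero at `R = L` and grows monotonically as the ends approach; for small
#' retraction it follows `fE * (L - R)` (second-order transition
#' energetics).
#'
#' @param chain a [chain_spec()] or dimensionless length `N`.
#' @param R end-to-end distance, `0 < R <= L` (in the chain's length units;
#'   `2lp` units when a bare `N` is given).
#' @param n_s number of arclength samples of the tangent angle.
#' @return object of class `elastica_solution`: list with `f` (the
#'   conjugate force on the buckled branch), `extension = R/L`, `s`,
#'   `theta` (tangent angle along arclength), `bend_energy` (kBT units) and
#'   the elliptic modulus `m`.
#' @examples
#' sol <- min_bend_energy_at_R(0.25, 0.9 * 0.25)
#' sol$bend_energy
#' @export
min_bend_energy_at_R <- function(chain, R, n_s = 201L) {
  N <- .as_N(chain)
  L <- N; kappa <- 0.5   # internal units
  if (R <= 0) stop("R must be positive")
  if (R > L * (1 + 1e-12)) stop("R exceeds the contour length (inextensible chain)")
  R <- min(R, L)
  s <- seq(0, L, length.out = n_s)
  if (R >= L * (1 - 1e-14)) {
    return(structure(list(chain = chain, f = 0, extension = 1, s = s,
                          theta = rep(0, n_s), bend_energy = 0, m = 0),
                     class = "elastica_solution"))
  }
  # solve 2 E(m)/K(m) - 1 = R/L (left side decreases from 1 as m grows)
  m <- uniroot(function(m) {
    ke <- pracma::ellipke(m)
    2 * ke$e / ke$k - 1 - R / L
  }, lower = 1e-14, upper = 1 - 1e-14, tol = 1e-14)$root
  ke <- pracma::ellipke(m)
  K <- ke$k; E <- ke$e
  f <- 4 * kappa * K^2 / L^2
  Ebend <- (8 * kappa / L) * (K * E - K^2 + m * K^2)
  # shape: sin(theta/2) = sqrt(m) sn(K - q s, m), q = 2K/L
  q <- 2 * K / L
  sn <- pracma::ellipj(K - q * s, m)$sn
  theta <- 2 * asin(pmin(1, pmax(-1, sqrt(m) * sn)))
  structure(list(chain = chain, f = f, extension = R / L, s = s,
                 theta = theta, bend_energy = Ebend, m = m),
            class = "elastica_solution")
}

#' @export
print.elastica_solution <- function(x, ...) {
  cat("elastica: R/L =", format(x$extension, digits = 8),
      " f =", format(x$f, digits = 8),
      " E_bend =", format(x$bend_energy, digits = 8), "kBT\n")
  invisible(x)
}

# ---- brute-force discrete oracle -------------------------------------------

# energy and gradient of a planar discrete rod: segments of length ds with
# angles phi, quadratic hinge energy (kappa/(2 ds)) sum (dphi)^2. The
# fixed-force oracle uses dead (projection) loading f * sum ds cos(phi) --
# the convention of the classical buckled branch, which admits negative
# extension; descent from a small zero-mean perturbation stays on that
# branch. The fixed-R oracle constrains the end-to-end *distance*.
.rod_R <- function(phi, ds) ds * sqrt(sum(cos(phi))^2 + sum(sin(phi))^2)
.rod_energy <- function(phi, ds, kappa, f) {
  dphi <- diff(phi)
  kappa / (2 * ds) * sum(dphi^2) + f * ds * sum(cos(phi))
}
.rod_grad <- function(phi, ds, kappa, f) {
  n <- length(phi)
  g <- numeric(n)
  dphi <- diff(phi)
  g[1:(n - 1)] <- g[1:(n - 1)] - kappa / ds * dphi
  g[2:n] <- g[2:n] + kappa / ds * dphi
  g - f * ds * sin(phi)
}

# damped Newton on the stationarity equations of the discrete rod under
# dead load; the Hessian is tridiagonal (second-difference bending part
# plus a diagonal force part)
.rod_newton <- function(phi, ds, kappa, f, tol = 1e-13, maxit = 60) {
  n <- length(phi)
  kb <- kappa / ds
  for (it in seq_len(maxit)) {
    g <- .rod_grad(phi, ds, kappa, f)
    H <- matrix(0, n, n)
    dmain <- rep(2 * kb, n)
    dmain[1] <- dmain[n] <- kb
    diag(H) <- dmain - f * ds * cos(phi)
    H[cbind(1:(n - 1), 2:n)] <- -kb
    H[cbind(2:n, 1:(n - 1))] <- -kb
    step <- tryCatch(solve(H, g), error = function(e) g)
    mx <- max(abs(step))
    if (mx > 0.3) step <- step * 0.3 / mx     # damping
    phi <- phi - step
    if (mx < tol) break
  }
  phi
}

#' Discrete-segment minimizer of the loaded rod (independent oracle)
#'
#' Minimizes the energy of an `n_seg`-segment planar discrete rod under a
#' fixed compressive load by conjugate-gradient descent from a shallow
#' sinusoidal perturbation (the straight rod is a saddle above the Euler
#' force). Serves as a brute-force cross-check of the elliptic-integral
#' solution, fully independent of elliptic functions.
#'
#' @param chain a [chain_spec()] or dimensionless length `N`.
#' @param f compressive force (internal units when a bare `N` is given).
#' @param n_seg number of segments.
#' @return list with `extension` (R/L), `bend_energy`, `phi` (segment
#'   angles).
#' @export
elastica_discrete <- function(chain, f, n_seg = 201L) {
  N <- .as_N(chain)
  L <- N; kappa <- 0.5
  ds <- L / n_seg
  smid <- (seq_len(n_seg) - 0.5) * ds
  fE <- euler_force(N)
  # descend from a small zero-mean perturbation at f >= 2 fE, where the
  # buckled branch is the direct attractor of the line-search methods, then
  # continue in force to the target with damped Newton steps: Newton from
  # an on-branch seed converges to the nearby branch solution and cannot
  # wander to the trivial reversed-rod state
  phi0 <- 0.05 * cos(pi * smid / L)   # hinged first mode: zero end moment
  f_start <- max(f, 2 * fE)
  en <- function(phi) .rod_energy(phi, ds, kappa, f_start)
  gr <- function(phi) .rod_grad(phi, ds, kappa, f_start)
  o1 <- optim(phi0, en, gr, method = "CG",
              control = list(maxit = 20000, reltol = 1e-14))
  phi <- optim(o1$par, en, gr, method = "BFGS",
               control = list(maxit = 10000, reltol = 1e-14))$par
  phi <- .rod_newton(phi, ds, kappa, f_start)
  if (f < f_start)
    for (fi in seq(f_start, f, length.out = 15)[-1])
      phi <- .rod_newton(phi, ds, kappa, fi)
  dphi <- diff(phi)
  list(extension = ds * sum(cos(phi)) / L,
       bend_energy = kappa / (2 * ds) * sum(dphi^2),
       phi = phi)
}

#' Discrete-segment constrained minimizer at fixed end-to-end distance
#'
#' Brute-force counterpart of [min_bend_energy_at_R()]: minimizes the
#' discrete bending energy subject to `R(phi) = R` by a quadratic-penalty
#' continuation (penalty weight ramped over several stages).
#'
#' @inheritParams elastica_discrete
#' @param R target end-to-end distance (internal units for a bare `N`).
#' @return list with `extension`, `bend_energy`, `phi`.
#' @export
elastica_discrete_R <- function(chain, R, n_seg = 201L) {
  N <- .as_N(chain)
  L <- N; kappa <- 0.5
  ds <- L / n_seg
  smid <- (seq_len(n_seg) - 0.5) * ds
  pen_e <- function(phi, mu) {
    dphi <- diff(phi)
    kappa / (2 * ds) * sum(dphi^2) + mu * (.rod_R(phi, ds) - R)^2
  }
  pen_g <- function(phi, mu) {
    n <- length(phi)
    g <- numeric(n)
    dphi <- diff(phi)
    g[1:(n - 1)] <- g[1:(n - 1)] - kappa / ds * dphi
    g[2:n] <- g[2:n] + kappa / ds * dphi
    Sx <- sum(cos(phi)); Sy <- sum(sin(phi))
    hyp <- sqrt(Sx^2 + Sy^2)
    if (hyp > 1e-12)
      g <- g + 2 * mu * (.rod_R(phi, ds) - R) * ds *
           (-Sx * sin(phi) + Sy * cos(phi)) / hyp
    g
  }
  # start from the circular arc with matching chord
  arc <- .arc_angle(R / L)
  phi <- if (arc == 0) 0.02 * cos(pi * smid / L)
         else arc * (smid / L - 0.5)
  base <- kappa / L   # energy scale for the penalty ramp
  for (mu in base * c(1e2, 1e4, 1e6, 1e8) / L^2) {
    en <- local({ m <- mu; function(phi) pen_e(phi, m) })
    gr <- local({ m <- mu; function(phi) pen_g(phi, m) })
    opt <- optim(phi, en, gr, method = "BFGS",
                 control = list(maxit = 20000, reltol = 1e-15))
    phi <- opt$par
  }
  dphi <- diff(phi)
  list(extension = .rod_R(phi, ds) / L,
       bend_energy = kappa / (2 * ds) * sum(dphi^2),
       phi = phi)
}

# arc angle of a circular arc with chord/arclength ratio rho: solves
# 2 sin(a/2)/a = rho; returns 0 for a straight segment
.arc_angle <- function(rho) {
  if (rho >= 1 - 1e-14) return(0)
  uniroot(function(a) 2 * sin(a / 2) / a - rho,
          lower = 1e-10, upper = 2 * pi - 1e-10, tol = 1e-14)$root
}
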