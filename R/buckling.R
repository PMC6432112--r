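# Finite-temperature buckling: compressive free-energy landscapes
# F(r)/kBT = -log(r^2 G(r;N)) + f r, their minima Rmin(f), the response
# function alphaF = -dRmin/df, and the critical force fc (argmax of
# alphaF, i.e. the inflection point of Rmin versus f).

#' Compressive free-energy profile of a worm-like chain
#'
#' Builds `F(r)/kBT = -log(r^2 G(r;N)) + f*r` on the interior grid of the
#' exact radial Green function. The additive constant is fixed by the
#' normalized `G` (no further shifting); profiles at two forces differ by
#' exactly `(f2 - f1)*r`.
#'
#' @param N dimensionless chain length (or a [chain_spec()]).
#' @param f dimensionless compressive force in `kBT/(2lp)` units (negative
#'   values = tension).
#' @param green optional precomputed [greens_r_N()] result for this `N`
#'   (reused across forces by the sweep drivers).
#' @param ... passed to [greens_r_N()] when `green` is `NULL`.
#' @return object of class `wlc_fprofile`: list with `N`, `f`, `r`,
#'   `F_values`, `Ef_values` (`= f*r`), `F0` (`-log r^2 G`).
#' @examples
#' g <- greens_r_N(0.25)
#' pr <- free_energy_profile(0.25, f = 0, green = g)
#' @export
free_energy_profile <- function(N, f, green = NULL, ...) {
  N <- .as_N(N)
  if (is.null(green)) green <- greens_r_N(N, ...)
  stopifnot(inherits(green, "wlc_green"), abs(green$N - N) < 1e-12)
  structure(list(N = N, f = f, r = green$r, F0 = green$F0,
                 Ef_values = f * green$r,
                 F_values = green$F0 + f * green$r),
            class = "wlc_fprofile")
}

#' @export
print.wlc_fprofile <- function(x, ...) {
  mn <- minimize_profile(x)
  cat("free-energy profile: N =", x$N, " f =", x$f, "\n")
  cat("  Rmin =", format(mn$Rmin, digits = 8),
      " (Rmin/L =", format(mn$Rmin / x$N, digits = 6), ")\n")
  invisible(x)
}

#' Locate the free-energy minimum of a profile
#'
#' Global minimum over the interior grid, refined by quadratic
#' interpolation through the best grid point and its neighbours. Grid-edge
#' minima are flagged (`boundary = TRUE`); ties are broken toward larger
#' `r` (the extended state) and flagged.
#'
#' @param profile a [free_energy_profile()] result, or any list with
#'   numeric `r` and `F_values`.
#' @return list with `Rmin`, `F_min`, `curvature` (d2F/dr2 at the minimum,
#'   a degeneracy diagnostic for the flat post-buckling profiles),
#'   `boundary`, `tie`.
#' @examples
#' pr <- list(r = seq(0.01, 0.99, length.out = 201),
#'            F_values = (seq(0.01, 0.99, length.out = 201) - 0.2)^2)
#' minimize_profile(pr)$Rmin          # ~ 0.2
#' @export
minimize_profile <- function(profile) {
  r <- profile$r
  Fv <- profile$F_values
  stopifnot(length(r) == length(Fv), length(r) >= 3)
  fin <- is.finite(Fv)
  idx <- which(fin)
  i0 <- idx[which.min(Fv[idx])]
  tie <- sum(Fv[idx] == Fv[i0]) > 1
  if (tie) i0 <- max(idx[Fv[idx] == Fv[i0]])
  if (i0 == idx[1] || i0 == idx[length(idx)]) {
    # at the edge of the finite range: a true grid edge means the r grid is
    # too narrow; an interior edge is the resolution boundary of the masked
    # landscape (the minimum is pinned there)
    at_grid_edge <- i0 == 1L || i0 == length(r)
    return(list(Rmin = r[i0], F_min = Fv[i0], curvature = NA_real_,
                boundary = at_grid_edge, tie = tie, pinned = TRUE))
  }
  # quadratic refinement through the three bracketing points (skipped when
  # a neighbour is masked/non-finite, e.g. at the resolution boundary of
  # the free-energy landscape)
  x <- r[(i0 - 1):(i0 + 1)]
  y <- Fv[(i0 - 1):(i0 + 1)]
  if (!all(is.finite(y))) {
    return(list(Rmin = r[i0], F_min = Fv[i0], curvature = NA_real_,
                boundary = FALSE, tie = tie, pinned = TRUE))
  }
  d1 <- (y[3] - y[1]) / (x[3] - x[1])
  d2 <- 2 * ((y[3] - y[2]) / (x[3] - x[2]) - (y[2] - y[1]) / (x[2] - x[1])) /
        (x[3] - x[1])
  rmin <- if (d2 > 0) x[2] - d1 / d2 else x[2]
  rmin <- min(max(rmin, x[1]), x[3])
  Fmin <- y[2] - if (d2 > 0) d1^2 / (2 * d2) else 0
  list(Rmin = rmin, F_min = Fmin, curvature = d2, boundary = FALSE,
       tie = tie, pinned = FALSE)
}

#' Force-extension curve and critical force of a fluctuating chain
#'
#' Maps the minimum free-energy end extension `Rmin` over a grid of
#' compressive forces, computes the response function
#' `alphaF = -dRmin/df` from a cubic-spline representation of `Rmin(f)`,
#' and extracts the critical force `fc` as the (quadratically refined)
#' argmax of `alphaF`. `fc` is the finite-temperature analogue of the
#' Euler force: the inflection point of the smooth `Rmin(f)` curve.
#'
#' @param N dimensionless chain length (or [chain_spec()]).
#' @param f_grid force grid in `kBT/(2lp)` units; default `n_f` points
#'   spanning `f_span * fE(N)`. Must bracket the response maximum.
#' @param n_f number of force-grid points.
#' @param f_span default span in units of the Euler force.
#' @param green optional precomputed [greens_r_N()] for this `N`.
#' @param ... passed to [greens_r_N()].
#' @return object of class `wlc_fx`: list with `N`, `f_grid`, `Rmin`
#'   (2lp units), `Rmin_over_L`, `alphaF`, `fE`, `fc`, `fc_over_fE`,
#'   `curvature` (profile curvature at each minimum).
#' @examples
#' \donttest{
#' fx <- force_extension(0.5)
#' fx$fc_over_fE        # > 1: fluctuations stabilize against buckling
#' }
#' @export
force_extension <- function(N, f_grid = NULL, n_f = 121L, f_span = c(-1, 4),
                            green = NULL, ...) {
  N <- .as_N(N)
  fE <- euler_force(N)
  if (is.null(f_grid)) f_grid <- seq(f_span[1], f_span[2], length.out = n_f) * fE
  stopifnot(!is.unsorted(f_grid), length(f_grid) >= 7)
  if (is.null(green)) green <- greens_r_N(N, ...)
  r <- green$r
  F0 <- green$F0
  Rmin <- numeric(length(f_grid))
  curv <- numeric(length(f_grid))
  pinned <- logical(length(f_grid))
  for (i in seq_along(f_grid)) {
    mn <- minimize_profile(list(r = r, F_values = F0 + f_grid[i] * r))
    if (mn$boundary)
      warning("free-energy minimum at the grid edge for f = ", f_grid[i],
              " (N = ", N, "); r grid too narrow there")
    Rmin[i] <- mn$Rmin
    curv[i] <- mn$curvature
    pinned[i] <- mn$pinned
  }
  # beyond the first pinned force the minimum sits at the resolution
  # boundary of the landscape (deep post-buckling states for stiff chains);
  # the response is analysed on the resolved branch only
  ilim <- if (any(pinned)) which(pinned)[1] - 1L else length(f_grid)
  ilim <- max(ilim, 8L)
  sf <- splinefun(f_grid[1:ilim], Rmin[1:ilim], method = "natural")
  fdense <- seq(f_grid[1], f_grid[ilim], length.out = 4001L)
  aF <- -sf(fdense, deriv = 1)
  imax <- which.max(aF)
  if (imax <= 2)
    stop("response maximum at the lower edge of the force grid; widen f_grid")
  at_pin <- ilim < length(f_grid) && imax >= length(fdense) - 1
  if (imax >= length(fdense) - 1 && !at_pin)
    stop("response maximum at the edge of the force grid; widen f_grid")
  if (at_pin) {
    # the resolvable response keeps rising up to the resolution limit:
    # the transition coincides with that limit to within the grid step
    fc <- fdense[imax]
  } else {
    # quadratic refinement of the argmax (vertex of the local parabola)
    x <- fdense[(imax - 1):(imax + 1)]
    y <- aF[(imax - 1):(imax + 1)]
    h <- x[2] - x[1]
    denom <- y[1] - 2 * y[2] + y[3]
    fc <- if (denom < 0) x[2] + 0.5 * h * (y[1] - y[3]) / denom else x[2]
  }
  aF_grid <- rep(NA_real_, length(f_grid))
  aF_grid[1:ilim] <- -sf(f_grid[1:ilim], deriv = 1)
  structure(list(N = N, f_grid = f_grid, Rmin = Rmin, Rmin_over_L = Rmin / N,
                 alphaF = aF_grid, fE = fE, fc = fc,
                 fc_over_fE = fc / fE, curvature = curv, pinned = pinned,
                 fc_at_resolution_limit = at_pin),
            class = "wlc_fx")
}

#' @export
print.wlc_fx <- function(x, ...) {
  cat("force-extension: N =", x$N, "\n")
  cat("  fE =", format(x$fE, digits = 8),
      " fc =", format(x$fc, digits = 8),
      " fc/fE =", format(x$fc_over_fE, digits = 6), "\n")
  invisible(x)
}

#' Critical-force surface over chain length
#'
#' Sweeps the dimensionless chain length, computing for each `N` the exact
#' radial Green function once and the full force-extension curve from it,
#' and assembles the `(N, fE, fc, fc/fE)` table together with the
#' `Rmin/L(f/fE, N)` surface in long format. Per-`N` failures are reported
#' as warnings and leave `NA` rows rather than aborting the sweep.
#'
#' @param N_grid dimensionless lengths (within about `[0.01, 4]`).
#' @param n_f force-grid resolution per length.
#' @param f_span force span in units of `fE(N)`.
#' @param ... passed to [greens_r_N()].
#' @return list of class `wlc_surface`: `table` (data frame with columns
#'   `N`, `fE`, `fc`, `fc_over_fE`) and `surface` (long data frame with
#'   `N`, `f_over_fE`, `Rmin_over_L`).
#' @examples
#' \donttest{
#' cs <- critical_force_surface(c(0.25, 0.5, 1))
#' cs$table
#' }
#' @export
critical_force_surface <- function(N_grid, n_f = 121L, f_span = c(-1, 4), ...) {
  stopifnot(all(N_grid > 0))
  tab <- data.frame(N = N_grid, fE = vapply(N_grid, euler_force, numeric(1)),
                    fc = NA_real_, fc_over_fE = NA_real_)
  surf <- vector("list", length(N_grid))
  for (i in seq_along(N_grid)) {
    Ni <- N_grid[i]
    fx <- tryCatch(force_extension(Ni, n_f = n_f, f_span = f_span, ...),
                   error = function(e) {
                     warning("N = ", Ni, " failed: ", conditionMessage(e))
                     NULL
                   })
    if (is.null(fx)) next
    tab$fc[i] <- fx$fc
    tab$fc_over_fE[i] <- fx$fc_over_fE
    surf[[i]] <- data.frame(N = Ni, f_over_fE = fx$f_grid / fx$fE,
                            Rmin_over_L = fx$Rmin_over_L)
  }
  structure(list(table = tab, surface = do.call(rbind, surf)),
            class = "wlc_surface")
}

#' @export
print.wlc_surface <- function(x, ...) {
  cat("critical-force surface over", nrow(x$table), "chain lengths\n")
  print(x$table)
  ok <- is.finite(x$table$fc_over_fE)
  if (any(ok))
    cat("max stabilization: ",
        format(100 * (max(x$table$fc_over_fE[ok]) - 1), digits = 4),
        "% above the Euler force\n", sep = "")
  invisible(x)
}
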