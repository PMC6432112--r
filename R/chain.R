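#' Physical parameters of a worm-like chain
#'
#' Bundles the contour length `L`, persistence length `lp` and thermal
#' energy `kBT` of a worm-like chain together with their dimensionless
#' reductions: the chain length `N = L/(2*lp)` and the bending modulus
#' `kappa = lp*kBT`. Either supply `L` and `lp` (any consistent length
#' unit), or supply `N` alone, in which case the chain is represented in
#' internal units (`lp = 1/2`, `kBT = 1`, so `L = N`).
#'
#' @param L contour length (length units); optional if `N` is given.
#' @param lp persistence length (same length units as `L`).
#' @param kBT thermal energy; defaults to 1 (energies in units of kBT).
#' @param N dimensionless chain length `L/(2*lp)`; optional if `L`, `lp`
#'   are given.
#' @return An object of class `chain_spec`: a list with fields `L`, `lp`,
#'   `kBT`, `N`, `kappa`.
#' @examples
#' chain_spec(L = 25, lp = 50)     # N = 0.25
#' chain_spec(N = 1)
#' @export
chain_spec <- function(L = NULL, lp = NULL, kBT = 1, N = NULL) {
  if (is.null(N)) {
    if (is.null(L) || is.null(lp))
      stop("supply either N, or both L and lp")
    N <- L / (2 * lp)
  } else {
    if (!is.null(L) || !is.null(lp)) {
      if (is.null(L) || is.null(lp))
        stop("supply either N alone, or both L and lp")
      if (abs(N - L / (2 * lp)) > 1e-12 * N)
        stop("inconsistent N and L/(2*lp)")
    } else {
      lp <- 0.5
      L <- N
    }
  }
  if (L <= 0 || lp <= 0 || kBT <= 0) stop("L, lp and kBT must be positive")
  structure(list(L = L, lp = lp, kBT = kBT, N = N, kappa = lp * kBT),
            class = "chain_spec")
}

#' @export
print.chain_spec <- function(x, ...) {
  cat("worm-like chain: L =", x$L, " lp =", x$lp, " kBT =", x$kBT, "\n")
  cat("  N = L/(2 lp) =", x$N, "  kappa = lp kBT =", x$kappa, "\n")
  invisible(x)
}

.as_N <- function(chain) {
  if (inherits(chain, "chain_spec")) chain$N
  else if (is.numeric(chain) && length(chain) == 1 && chain > 0) chain
  else stop("expected a chain_spec or a positive dimensionless length N")
}

#' Convert between dimensional and internal chain units
#'
#' Exact algebraic conversion between laboratory units and the internal
#' dimensionless system (lengths in 2*lp, forces in kBT/(2*lp), energies in
#' kBT), using the chain's `lp` and `kBT`. For force conversions `kBT` is
#' interpreted in pN*length units consistent with `lp` (e.g. kBT = 4.1 pN nm
#' with lp in nm).
#'
#' @param value numeric value(s) to convert.
#' @param from,to unit labels; one of `"nm"`, `"2lp"` (lengths), `"pN"`,
#'   `"kBT/2lp"` (forces), `"J"`, `"kBT"` (energies).
#' @param chain a [chain_spec()] providing `lp` and `kBT`.
#' @return converted numeric value(s).
#' @examples
#' ch <- chain_spec(L = 25, lp = 50, kBT = 4.1)  # kBT in pN nm
#' unit_convert(25, "nm", "2lp", ch)             # 0.25
#' unit_convert(1, "kBT/2lp", "pN", ch)          # 0.041
#' @export
unit_convert <- function(value, from, to, chain) {
  stopifnot(inherits(chain, "chain_spec"))
  kind <- function(u) switch(u,
    "nm" = "length", "2lp" = "length",
    "pN" = "force", "kBT/2lp" = "force",
    "J" = "energy", "kBT" = "energy",
    stop("unknown unit: ", u))
  if (kind(from) != kind(to))
    stop("incompatible units: ", from, " -> ", to)
  if (from == to) return(value)
  two_lp <- 2 * chain$lp
  switch(kind(from),
    length = if (from == "nm") value / two_lp else value * two_lp,
    force  = if (from == "pN") value * two_lp / chain$kBT
             else value * chain$kBT / two_lp,
    energy = if (from == "J") value / (chain$kBT * 1e-21)
             else value * chain$kBT * 1e-21)
}
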