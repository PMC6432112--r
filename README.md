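# wlcbuckle

Exact statistical mechanics of buckling for a fluctuating worm-like chain
(WLC) under compressive load.

Semiflexible biopolymers — DNA, actin, microtubules — buckle under
piconewton compressive forces that are comparable to thermal forces, so
the classical Euler analysis (valid at zero temperature) is not enough,
and approximate fluctuation treatments disagree even on the *sign* of the
thermal shift of the critical force. This package settles the question
with exact WLC statistics: thermal fluctuations **raise** the critical
buckling force above the Euler force, by as much as ~80% for chains a few
persistence lengths long, and turn the sharp second-order transition into
a smooth, compliant one.

## What it computes

With lengths in units of `2*lp`, energies in `kBT`, forces in
`kBT/(2*lp)`, and `N = L/(2*lp)`:

* **Exact end-to-end distribution** `G(r;N)` from the continued-fraction
  Green function

  `G(K;p) = 1/(P0 + (a1 K)^2/(P1 + (a2 K)^2/(P2 + ...)))`,
  `P_l = p + l(l+1)`, `a_l = l/sqrt((2l+1)(2l-1))`,

  inverted by a pole/residue expansion in the Laplace variable (poles
  continued along `K`, verified against eigendecompositions, with a
  Talbot contour as an independent cross-check) and an oscillatory
  Fourier quadrature with an analytic sparse-sample tail
  (`continued_fraction()`, `find_poles()`, `greens_K_N()`,
  `greens_r_N()`).
* **Compressive free-energy landscapes** `F/kBT = -log(r^2 G) + f r`,
  their minima `Rmin(f)`, the response function `alphaF = -dRmin/df`, and
  the critical force `fc` as the response maximum
  (`free_energy_profile()`, `force_extension()`,
  `critical_force_surface()`).
* **Zero-temperature reference**: the hinged-rod Euler force
  `fE = pi^2 kappa / L^2`, the buckled elastica force–extension curve and
  the constrained minimal bending energy via complete elliptic integrals,
  cross-checked by brute-force discrete-rod minimizers (`euler_force()`,
  `elastica_extension()`, `min_bend_energy_at_R()`).
* **Seeded Metropolis Monte Carlo** of the bead-discretized chain in
  fixed-extension (crankshaft moves, ends conserved exactly) and
  fixed-force (crankshaft + end-pivot) ensembles, with block-averaged
  errors and the energy/entropy decomposition
  `TS = <Epoly> - E0 - F` (`build_chain()`, `mc_fixed_R()`,
  `mc_fixed_f()`, `thermo_sweep()`).

## Worked example

```r
library(wlcbuckle)

## force-extension and critical force of a chain one persistence length
## long (N = L/(2 lp) = 0.5)
fx <- force_extension(0.5)
fx
#> force-extension: N = 0.5
#>   fE = 19.739209  fc = 25.063826  fc/fE = 1.2697

## the fluctuating chain withstands 27% more compression than the
## zero-temperature Euler rod before buckling.

## sweep chain lengths: the stabilization grows to ~80%
cs <- critical_force_surface(seq(0.25, 2, length.out = 15))
cs
#> critical-force surface over 15 chain lengths
#>        N      fE       fc fc_over_fE
#> 1  0.250 78.9568  90.8845     1.1511
#> ...
#> 14 1.875  1.4037   2.5082     1.7869
#> 15 2.000  1.2337   2.1949     1.7791
#> max stabilization: 78.69% above the Euler force

## exact radial end-to-end density at N = 0.25, with its built-in checks
g <- greens_r_N(0.25)
g
#> WLC radial Green function, N = 0.25
#>   grid: 400 points on (0, 0.25)
#>   normalization: 1           <r^2>: 0.053265329 (exact 0.053265329)

## seeded Monte Carlo of a 51-bead chain at fixed extension
run <- mc_fixed_R(build_chain(0.25, 51, R_init = 0.2), seed = 42)
run
#> MC run ( fixed_R ): N = 0.25  Nb = 51  constraint = 0.2
#>   <Epoly> = 52.3 +/- 0.07 kBT  acceptance = 0.4
```

A command-line front end mirrors these entry points
(`inst/cli/wlcbuckle greens --N 1 --out g.csv`,
`... critical --N-min 0.25 --N-max 2 --out fc.csv`,
`... mc --N 0.25 --Nb 51 --ensemble fixed-R --R 0.2 --seed 42 --out run.json`,
`... reproduce fig2|fig3 --out out.csv`), writing CSV with 17 significant
digits, JSON metadata sidecars and XYZ conformation snapshots.

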