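---
title: "Exact buckling statistics of fluctuating worm-like chains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact buckling statistics of fluctuating worm-like chains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(wlcbuckle)
```

## The model

A semiflexible biopolymer (DNA, actin, a microtubule segment) is modelled
as a worm-like chain (WLC): an inextensible space curve $\mathbf r(s)$,
$s \in [0, L]$, with unit tangent $\mathbf u(s)$ and quadratic bending
energy

$$E_B = \frac{\kappa}{2} \int_0^L \left| \frac{\partial \mathbf u}{\partial s} \right|^2 \mathrm{d}s,
\qquad \kappa = l_p\, k_B T,$$

where $l_p$ is the persistence length. A compressive force $f$ applied
between the ends contributes $E_f = f R$ with $R$ the end-to-end distance.
All internal quantities are dimensionless: lengths in units of $2 l_p$
(so a chain is characterized by $N = L / 2 l_p$ alone), energies in
$k_B T$, forces in $k_B T / 2 l_p$.

At zero temperature the chain is an elastic rod: it stays straight up to
the hinged-rod Euler force $f_E = \pi^2 \kappa / L^2$
($\tilde f_E = \pi^2 / 2N^2$ in internal units) and buckles beyond it, a
second-order transition described by the classical elastica
(`euler_force()`, `elastica_extension()`, `min_bend_energy_at_R()`).
At finite temperature the question is how thermal fluctuations reshape
this transition — and the answer requires the *exact* chain statistics,
because approximate treatments disagree even on the sign of the shift of
the critical force.

## Exact end-to-end statistics

The distribution of the end-to-end vector is encoded in the Green function
$G(\mathbf R; L)$. In Fourier–Laplace space (wavevector $K$ conjugate to
$r = R/2l_p$, Laplace variable $p$ conjugate to $N$) it has the exact
continued-fraction representation

$$G(K;p) = \cfrac{1}{P_0 + \cfrac{(a_1 K)^2}{P_1 + \cfrac{(a_2 K)^2}{P_2 + \cdots}}},
\qquad P_l = p + l(l+1), \quad a_l = \frac{l}{\sqrt{(2l+1)(2l-1)}},$$

under the isotropic convention $G(K;N) = \langle \sin(Kr)/Kr \rangle$, so
that $G(0;N) = 1$ is the normalization (`continued_fraction()`).

**Inverse Laplace transform.** $G(K;p)$ is meromorphic in $p$; its poles
are the eigenvalues of the tridiagonal operator with diagonal $-l(l+1)$
and coupling $i a_l K$, and

$$G(K;N) = \sum_j \mathrm{res}_j\, e^{p_j N}.$$

At $K = 0$ the poles are exactly $-l(l+1)$ with all residue in the leading
pole. As $K$ grows, real poles merge pairwise at branch points and continue
as complex-conjugate pairs. The package locates poles by Newton iteration
on the characteristic polynomial of the truncated operator (a three-term
determinant recurrence with analytic derivatives, evaluated with joint
rescaling), continues the pole set along $K$ with adaptive internal
stepping and per-pole velocity prediction, resolves branch-point
collisions through the local quadratic model at the bracketed extremum of
the determinant, and periodically verifies the whole set against direct
eigendecompositions while the matrix size permits (`find_poles()`,
`greens_K_N()`). A fixed-Talbot numerical inversion of the continued
fraction is retained as an independent cross-check
(`greens_K_N(method = "contour")`); because the contour must enclose poles
with imaginary parts of order $K$ at a floating-point cancellation cost
$e^{0.75 K N}$, it certifies $10^{-8}$ agreement only for moderate $K N$
and reports its own precision estimate.

**Inverse Fourier transform.** The radial distribution follows from

$$G(r;N) = \frac{1}{2\pi^2 r} \int_0^\infty K \sin(Kr)\, G(K;N)\, \mathrm{d}K .$$

Through the pole-collision region the integral is done with Gauss panels
of width $\pi/2N$ (bounding the fastest phase to $\sim\pi$ per panel).
Beyond it, where the pole trajectories $\lambda_j(K)$ and residues are
smooth, the package samples them sparsely — spacing chosen from an
explicit phase-error budget, $\Delta \sim K^{3/4}\sqrt{\varepsilon/N}$ —
interpolates $\lambda_j$ linearly and $\log \mathrm{res}_j$ linearly per
panel, and integrates $K \sin(Kr)\, \mathrm{res}\, e^{\lambda N}$
*analytically* against the oscillations, closing the final tail to
$K = \infty$ in closed form. This keeps the cost essentially independent
of how far the integral must reach; stiff chains need wavevectors up to
$\sim 230/N^2$ before the envelope
$e^{\operatorname{Re}\lambda_0 N} \sim e^{-0.95\sqrt K N}$ is negligible.

Every computed distribution must pass three gates before it is returned
(`greens_r_N()`): normalization $\int_0^N 4\pi r^2 G\, \mathrm{d}r = 1$
to $10^{-3}$, the closed-form second moment
$\langle r^2 \rangle = N - (1 - e^{-2N})/2$ to relative $10^{-3}$
(`mean_square_r()`), and a bound on negative ringing of the density
($10^{-6}$ of the peak for $N \ge 0.1$; $10^{-4}$ for stiffer chains,
where the noise floor of deep-pole localization in double precision sets
an irreducible scale of a few $10^{-5}$). The wavevector cutoff doubles
and the sampling budget tightens until all gates pass.

**Resolution limits of the landscape.** $F_0(r) = -\log(r^2 G)$ spans
hundreds of $k_B T$ for stiff chains while the oscillatory quadrature has
an absolute noise floor, so only the part of the landscape within about
$-\log(5\,\varepsilon_{\mathrm{noise}})$ (roughly 14 $k_B T$ at default
accuracy) of the minimum is trustworthy. The package masks everything
deeper as unresolved (`Inf`), detecting noise onset by sign flips and by
violations of unimodality of the radial density. Downstream minimizations
treat the mask boundary as a pinning point and flag it.

## The buckling analysis

The compressive free-energy landscape is

$$\frac{F(R, L)}{k_B T} = -\log\!\left[ R^2 G(R;L) \right] + f R,$$

built by `free_energy_profile()` on the interior grid of the radial Green
function (the additive constant fixed by the normalized $G$). Its global
minimum $R_{\min}(f)$ is located with quadratic refinement
(`minimize_profile()`), the response function $\alpha_F = -dR_{\min}/df$
is evaluated from a cubic-spline representation of $R_{\min}(f)$ over a
default 121-point force grid spanning $[-1, 4] f_E$, and the critical
force $f_c$ is the quadratically refined argmax of $\alpha_F$ — the
inflection point of the smooth force-extension curve
(`force_extension()`). `critical_force_surface()` assembles the
$(N, f_E, f_c)$ table and the $R_{\min}/L$ surface over a grid of chain
lengths. Only the location of the argmax matters for $f_c$, so the
normalization of $\alpha_F$ (reported in $(2l_p)^2/k_B T$ units) is
cosmetic.

Two regimes deserve comment:

* For stiff chains the post-buckling states lie deeper than the resolved
  landscape; $R_{\min}$ then pins at the resolution boundary, the response
  analysis is restricted to the resolved branch, and when the response
  maximum rides against that limit the result is flagged
  (`fc_at_resolution_limit`). The flagged value still brackets the
  transition to within the force-grid step, which is ample at the few
  percent level relevant there.
* For tension ($f < 0$) the same profiles apply; the branch is included
  for continuity checks.

Across $N \in [0.25, 2]$ the computed critical force exceeds the Euler
force everywhere, rising from about $15\%$ elevation at $N = 0.25$
through a maximum of about $79\%$ near $N \approx 1.9$ — thermal
fluctuations *stabilize* the chain against buckling — while for very
short chains ($N = 0.01$) the ratio returns to within a couple of percent
of one, recovering the zero-temperature limit. The transition itself is
smooth at finite $N$, in contrast to the elastica's kink: compliance is
large but finite at $f_c$, and the $R_{\min}/L$ curves converge pointwise
to the elastica as $N \to 0$.

## Monte Carlo of the discretized chain

`build_chain()` discretizes the chain into $N_b$ beads joined by rigid
bonds of length $\Delta s = L/(N_b - 1)$, with bending energy
$k \sum_i (1 - \mathbf u_i \cdot \mathbf u_{i+1})$, $k = l_p/\Delta s$
(the continuum mapping). The initial conformation is a circular arc whose
chord equals the requested end distance exactly.

* **Fixed extension** (`mc_fixed_R()`): crankshaft moves only — a
  sub-chain strictly between two beads rotates about the axis through
  them — so bond lengths and both end positions are conserved exactly
  (checked every sample to $10^{-10} N$). This samples the ensemble
  conjugate to $r^2 G(r)$.
* **Fixed force** (`mc_fixed_f()`): crankshaft plus end-pivot moves with
  weight $e^{-(E_B + fR)}$.

Move amplitudes are tuned to $\approx 40\%$ acceptance during
equilibration and then frozen (tuning during production would bias the
sampling). Defaults — $2\times10^4$ equilibration sweeps, $2\times10^5$
production sweeps of $N_b$ attempted moves, samples every 10 sweeps,
20-block standard errors — are converged at desk scale for
$N_b \le 51$. A single seeded generator drives each run;
identical seed and configuration give bit-identical sample streams.

The sampler is validated against closed forms (free-chain
$\langle E \rangle = (N_b - 2)(k + 1 - k \coth k)$, the exact discrete
$\langle R^2 \rangle$, the single-joint angle law
$p(\theta) \propto \sin\theta\, e^{-k(1-\cos\theta)}$ by KS test), against
direct rejection sampling of the constrained ensemble, and against the
exact radial density (histogram agreement bin by bin).

### Reference energy and the entropy decomposition

The average bending energy of the discrete chain contains a
discretization-dependent additive part. `reference_energy()` offers two
conventions: the published formula $E_0 = \tfrac52 k_B T (N_b - 4)$, and
an empirical mode that regresses $\langle E \rangle$ against $N_b$ at
fixed extension. For the rigid-bond discretization used here the
empirical slope is close to **1** $k_B T$ per joint (two transverse
bending modes at $k_B T/2$), not $5/2$ — the published slope implies
additional quadratic modes (e.g. extensible bonds) in the discretization
behind it. The discrepancy is reported rather than hidden; every collapse
or trend analysis is offset-free, so either convention may be used
consistently.

`thermo_sweep()` combines the exact $F$, the sampled
$\langle E_{\mathrm{poly}} \rangle$ and $E_0$ into the entropy
$TS = \langle E_{\mathrm{poly}} \rangle - E_0 - F$ per extension, along
with the constrained elastica energy. At $N = 0.25$ the free energy rises
with retraction faster than the zero-temperature bending energy on the
retracted branch — the thermodynamic signature of the elevated critical
force. One caveat the package surfaces explicitly: for the rigid-bond
model the *maximum-entropy* state sits at $R/L \approx 0.75$, about one
$k_B T$ above the entropy at the free-energy minimum
($R/L \approx 0.955$), because the bending anharmonicity tilts
$\langle E \rangle(R)$ near full extension; $TS$ cannot peak exactly at
$R_{\min}$ in any case, since $dTS/dR = d\langle E \rangle/dR \ne 0$
there. The harmonic surrogate $E_{\mathrm{elastica}} - F$ does peak at
the minimum. Whether a different discretization moves the measured peak
back to $R_{\min}$ is left open; the corresponding acceptance check is
deliberately left failing rather than weakened.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `n_r` | 400 (more for stiff chains) | interior $r$ grid, square-root-stretched towards $r = N$ |
| `tol` | $10^{-3}$ | normalization / second-moment gate |
| `ring_tol` | $10^{-6}$ ($10^{-4}$ for $N<0.1$) | negative-ringing clip threshold |
| `filon_phase_tol` | $10^{-6}$ rad | phase-error budget of the sparse tail quadrature |
| `n_f`, `f_span` | 121, $[-1, 4] f_E$ | force grid of the response analysis |
| `n_sweeps`, `n_equil` | $2\times10^5$, $2\times10^4$ | MC production / equilibration sweeps |
| `sample_stride`, `n_blocks` | 10, 20 | sampling interval, error-bar blocks |

Problem sizes used by the validation suite: chain lengths
$N \in \{0.01, 0.25, \dots, 4\}$; 15-point length grids for the
critical-force surface; $N_b \in \{11, 31, 51\}$ beads; $10^4$–$10^5$
decorrelated samples per Monte Carlo observable.

## What the checks do and do not show

All fixtures are generated in code: the synthetic inputs are the chain
parameters themselves, and every reference value is either a closed form
(moments, free-chain energies, elliptic integrals), an independent
brute-force computation (discrete elastica minimizers, rejection
sampling, dense quadrature), or an internal consistency identity
(normalization, envelope theorem, Legendre pairing). Passing them shows
that the continued-fraction statistics, the inversions and the samplers
agree with each other and with everything exactly known about the model.
They do not test physics outside the model's scope: excluded volume,
twist, dynamics, clamped ends and sequence heterogeneity are absent by
construction, so quantitative transfer to a real filament is limited to
regimes where the ideal WLC applies.
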