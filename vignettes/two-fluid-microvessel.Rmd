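---
title: "A two-fluid model of microvessel blood flow: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-fluid model of microvessel blood flow: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(hemoflow)
```

## The model and its assumptions

`hemoflow` treats blood in arteriole-scale vessels as two interpenetrating
continua in the sense of mixture theory: a Newtonian plasma phase with
volume fraction $1-\phi$ and an RBC phase with volume fraction $\phi$ (the
local hematocrit). Both phases share a single pressure $p$; each carries its
own velocity field and stress tensor, and they exchange momentum through
drag and lift forces. The steady phase continuity and momentum balances are

$$\nabla\cdot[(1-\phi)\mathbf v_p] = 0,\qquad
  \nabla\cdot(\phi\,\mathbf v_r) = 0,$$
$$(1-\phi)\rho_p(\mathbf v_p\cdot\nabla)\mathbf v_p =
  \nabla\cdot\mathbf T_p + (1-\phi)\rho_p\mathbf b_p + \mathbf f_I,\qquad
  \phi\rho_r(\mathbf v_r\cdot\nabla)\mathbf v_r =
  \nabla\cdot\mathbf T_r + \phi\rho_r\mathbf b_r - \mathbf f_I,$$

with $\mathbf T_p = -p(1-\phi)\mathbf I + 2\mu_p(1-\phi)\mathbf D_p$ and
$\mathbf T_r = [-p\phi + \lambda_r\phi\,\mathrm{tr}\,\mathbf D_r]\mathbf I
+ 2\mu_r\phi\mathbf D_r$. The plasma bulk-viscosity term never enters
because $\mathrm{tr}\,\mathbf D_p = 0$ for the incompressible plasma; the
RBC second viscosity $\lambda_r$ has no established value for this model,
so it defaults to 0 and is exposed as a knob in
`rheology_coefficients()`.

Assumptions worth keeping in sight: the RBC population is a continuum (no
individual cell dynamics, no membranes, no rouleaux kinetics); the flow is
steady and laminar; the geometry is a half-domain (axisymmetric tube for
the stenosis, planar symmetric channel for the expansion); walls are rigid
and no-slip for both phases.

### RBC rheology

The RBC-phase viscosity is a shear-thinning generalized-Newtonian law with
hematocrit-dependent limits,

$$\mu_r = \tfrac12\Big[\mu_\infty + (\mu_0-\mu_\infty)
  \frac{1+\ln(1+k\dot\gamma)}{1+k\dot\gamma}\Big](1+\phi),\qquad
  \dot\gamma = \sqrt{2\,\mathrm{tr}\,\mathbf D_r^2},$$

with $\mu_0(\phi) = 537.002\phi^2+55.006\phi-0.129$ cP,
$\mu_\infty(\phi) = 27.873\phi^2-21.218\phi+14.439$ cP and $k=11$ s, taken
as printed from viscometric fits to whole blood. Three consequences of
taking the fits literally are documented rather than patched away:

* the polynomials are dimensionally bare; this package interprets them in
  centipoise (consistent with the plasma viscosity being quoted in cP, and
  numerically identical to mPa·s) and converts to Pa·s internally;
* $\mu_0(\phi)$ is negative below $\phi\approx0.0023$, so every viscosity
  evaluation is floored at a configurable minimum (default one tenth of the
  plasma viscosity); the law is recommended for $\phi\in[0.05,0.6]$;
* the two fits cross near $\phi\approx0.11$: below that hematocrit
  $\mu_0<\mu_\infty$ and the law is locally shear-*thickening*. The
  monotone shear-thinning property and the
  $\tfrac12\mu_\infty(1+\phi)\le\mu_r\le\tfrac12\mu_0(1+\phi)$ bracketing
  hold on the $\mu_0>\mu_\infty$ branch and are asserted there.

### Interphase forces

`total_interaction()` sums three force densities, each Galilean-invariant
(they depend on velocities only through the slip $\mathbf v_r-\mathbf v_p$)
and each returned with the sign convention *added to the plasma balance,
subtracted from the RBC balance*, so pairwise closure is exact by
construction:

* **drag** $\frac{9\mu_p}{2a^2}f(\phi)(\mathbf v_r-\mathbf v_p)$ with the
  hindrance function $f(\phi)=\phi(1+6.55\phi)$ and $a=8$ µm the RBC size.
  The formula is used exactly as printed, with $a$ called a diameter even
  though the dilute Stokes prefactor conventionally uses a radius — fidelity
  to the printed model wins and the ambiguity is noted here;
* **Saffman shear-lift**
  $\frac{3\cdot6.46\sqrt{\rho_p\mu_p}}{4\pi a}\,\phi\,
  [2\,\mathrm{tr}\,\mathbf D_p^2]^{-1/4}\mathbf D_p(\mathbf v_r-\mathbf v_p)$.
  The $\dot\gamma_p^{-1/2}$ prefactor is singular in quiescent fluid, so the
  shear rate is floored at `shear_floor` (default $10^{-3}\,$s$^{-1}$),
  which keeps the term bounded and continuous;
* **spin-lift** $\tfrac34\rho_p\phi(\mathbf W_r-\mathbf W_p)
  (\mathbf v_r-\mathbf v_p)$, perpendicular to the slip in 2D because the
  spin difference is antisymmetric.

Virtual-mass, Basset and surface-tension forces are not implemented. The
hindrance correction multiplies only the drag, as printed. Gravity is an
optional uniform body force on both phases; the sudden-expansion validation
case enables it transverse to the flow ($-y$, 9.81 m/s²), emulating a
horizontal channel in which the denser RBC phase settles — the magnitude
and orientation are this package's assumption, since the benchmark
description only states that gravity is included.

## Geometries and grids

The stenosed vessel is axisymmetric with the cosine wall profile
$y(x) = \frac{H+h_s}{2}-\frac{H-h_s}{2}\cos(2\pi x/L_s)$ for
$|x|\le L_s/2$ and $y=H$ outside; defaults $H=50$ µm, $h_s=25$ µm,
$L_s=70$ µm ($\eta_h=0.5$, $\eta_L=1.4$) with 500 µm of straight vessel on
both sides of the throat. The sudden expansion is a planar half-channel,
50 µm half-height opening to 100 µm at $x=0$ (the printed 100/200 µm are
read as full channel heights; the half-model heights are configurable),
1 mm upstream and 2 mm downstream. Both cases solve half-domains with a
symmetry/axis boundary at $y=0$.

Grids are algebraic and body-fitted: each axial station's node column is a
scaled copy of $[0,1]$ mapped to $[0,y_\mathrm{wall}(x)]$ — sufficient for
the smooth cosine wall, with no elliptic smoothing. The expansion uses two
conforming blocks sharing the interface below the corner; the step face is
a wall. Cell and face metrics are exact polygon integrals; in axisymmetric
mode volumes and face areas are exact per-radian integrals of $r$, and the
per-cell closure identity $\sum_f \mathbf S_f = (0, A_\mathrm{planar})$
holds to machine precision (planar mode: zero).

Transverse clustering (`cluster_wall`) accepts both signs: positive
concentrates cells at the wall, negative at the core. The study runs use
`cluster_wall = -1.2` (core-clustered, coarser wall cells) with
`cluster_throat = 2.5`: systematic trials showed the segregated two-fluid
iteration diverges on this stenosis when the near-wall throat cells are
made thin (uniform and wall-clustered 120×24 grids diverge even in the
single-phase limit, while core-clustered grids converge to residuals of
$10^{-9}$), and the coarse-wall bias costs about 1% in the analytic
wall-shear-stress checks. The `mesh_independence_study()` operation is the
instrument for judging whether a chosen resolution is adequate, mirroring
the way grid convergence is usually established for these flows.

## Discretization and solution algorithm

The solver is a collocated finite-volume SIMPLE loop:

1. **Closures.** Green–Gauss cell gradients give $\mathbf D$, $\mathbf W$
   per phase (axisymmetric mode carries the hoop strain $v_y/y$); the RBC
   viscosity and the interphase forces are evaluated cell-wise.
2. **Phase momentum.** Convection uses implicit first-order upwind in the
   row-sum-zero (non-conservative) form matching the
   $(\mathbf v\cdot\nabla)\mathbf v$ statement of the balances, with an
   optional minmod-limited deferred correction (`scheme = "tvd"`, used by
   the study runs). Diffusion is implicit in its orthogonal part with
   face-interpolated $\mu_\mathrm{eff}\alpha$; the non-orthogonal remainder
   and the transpose (stress) part are explicit deferred corrections. The
   drag is implicit in the owned phase and explicit in the partner phase;
   lifts are explicit and under-relaxed against their previous iterate
   (`relax_force`, default 0.3) — without this the high-shear near-wall
   cells oscillate. Momentum under-relaxation is implicit
   (`relax_v = 0.7`).
3. **Pressure correction.** Mixture continuity
   $\nabla\cdot[(1-\phi)\mathbf v_p + \phi\mathbf v_r]=0$ is enforced by a
   SIMPLE pressure-correction equation on Rhie–Chow momentum-interpolated
   face fluxes (suppressing odd–even decoupling), with the outlet as the
   pressure reference (Dirichlet $p'=0$) and `relax_p = 0.3` on the
   pressure update; face fluxes are corrected fully, so cell-wise mixture
   continuity holds to linear-solver precision after every outer iteration.
4. **Volume fraction.** $\nabla\cdot(\phi\mathbf v_r)=0$ is solved
   implicitly with conservative upwind fluxes (upwinded by the RBC face
   flux), inlet Dirichlet $\phi=H_t$, zero wall/symmetry flux and a local
   pseudo-time diagonal (CFL-like factor `pseudo_cfl = 10`, scaled by the
   larger of a cell's in/out flux so transiently inflow-only cells stay
   well-conditioned). The update is under-relaxed (`relax_phi = 0.3`) and
   clipped to `phi_bounds` (default $[10^{-6}, 0.68]$; the upper bound is a
   random-close-packing-like limit, chosen here since the model itself
   states none); clipped mass is logged and bounded in the tests.

All linear systems are solved with sparse LU (`Matrix`), row-equilibrated
by their diagonal because thin cells and the $\phi$-weighting spread row
magnitudes over many decades. Convergence is declared when the normalized
residuals (velocity change over $V_t$, continuity imbalance over the inlet
flux, absolute change of the dimensionless $\phi$) all fall below `tol`. The iteration is
deterministic: identical inputs give bit-identical residual histories.

Boundary conditions follow the study setup: uniform axial inlet velocity
$V_t$ and inlet hematocrit $H_t$ for both phases (slip develops
internally), zero outlet pressure with zero-gradient outflow, no-slip walls
for both phases, symmetry/axis at $y=0$.

## Post-processing definitions

* **Wall shear stress** is the magnitude of the tangential component of the
  one-sided plasma-phase viscous traction,
  $\tau_\mathrm{wss} = |\mathbf t-(\mathbf t\cdot\mathbf n)\mathbf n|$ with
  $\mathbf t = 2\mu_p(1-\phi)\mathbf D_p\,\mathbf n$ built from the
  wall-adjacent cell velocity. A mixture-stress variant is available behind
  `use_mixture = TRUE` for sensitivity checks.
* **Section profiles** interpolate $\phi$ and the axial velocities onto a
  uniform transverse sampling, blending the two bracketing grid columns in
  the normalized coordinate $y/y_\mathrm{wall}$; the conventional sections
  are A ($x=-30$ µm), B (the throat) and C ($+30$ µm). **Section fluxes**
  have two instruments: `section_flux()` sums the scheme's own conservative
  face fluxes (exactly equal across sections on a converged state, which is
  the package's canonical conservation check), while integrating the
  interpolated profile carries a few percent of cell-to-face reconstruction
  error at the throat on desk-scale grids (about 4% at 120×24) — both are
  asserted in the tests at their respective accuracies.
* **Recirculation extent** is located by sign changes of the near-wall
  axial plasma velocity downstream of $x=0$, with linear interpolation
  between wall-adjacent cell centers.
* **Cell-free / cell-rich layers** are threshold definitions of regions the
  study literature judges from contour plots: cell-free where
  $\phi < 0.5\,H_t$, cell-rich where $\phi > 1.2\,H_t$ (both configurable),
  measured as wall-adjacent connected components with an axial extent and a
  maximum inward thickness. Any such quantification is an extrapolation of
  a verbal description and is labelled as such.

## Study conditions and problem sizes

The scripted experiments reproduce the study matrix: the stenosis sweep
runs $V_t\in\{0.1,0.2,0.4,0.8\}$ m/s at $H_t=20\%$ and
$H_t\in\{10\%,20\%,40\%\}$ at $V_t=0.2$ m/s; the expansion validation runs
$V_t=0.833$ m/s, $H_t=20\%$ with transverse gravity. Desk-scale default
grids are 120×20 for the stenosis sweep (90×14 in the test suite's trend
checks, 120×24 for the tightly converged conservation case) and a
(40+80)×(10/20) two-block grid for the expansion — orders of magnitude
below the ~160k-node meshes a commercial solver would use for these cases,
which is deliberate: the package's correctness case rests on analytic
limits (Poiseuille ratios and wall shear stress on 200×24 grids, at 2–3%),
exact conservation statements, and the study's qualitative/monotonic
findings, all of which are resolution-robust, rather than on reproducing
any field point-wise. The maximum-WSS-versus-$H_t$ direction is *reported*
(the package measures it as decreasing at desk scale) but not asserted,
because the study's own text states both directions in different places.

## What the tests do and do not show

Passing tests show: the constitutive laws and force terms match their
printed formulas and hand-computed values; the discrete operators are exact
on linear fields and convergent on the cosine wall; the solver recovers
single-phase Poiseuille limits within stated tolerances, conserves each
phase's mass to $10^{-6}$ and is deterministic; and the two-fluid physics
at desk scale reproduces the study's qualitative structure — WSS peaking
upstream of the throat and growing with $V_t$, a downstream recirculation
growing with $V_t$, a wall-adjacent cell-free region coinciding with it,
and a downstream cell-free layer plus corner recirculation in the
expansion benchmark.

They do not show: point-wise agreement with any reference field at
production mesh density, quantitative cell-free-layer thicknesses against
experiments, pulsatile or compliant-wall behaviour (out of scope by
design), or validity of the rheological fits outside
$\phi\in[0.05,0.6]$.

## Known limitations

* The segregated iteration requires core-clustered (coarse-wall) grids on
  the stenosis; wall-refined grids would need a coupled or more strongly
  implicit treatment of the lift and pressure coupling.
* Single-phase flow through the stenosis at the plasma viscosity (Reynolds
  number ≈ 40 in the throat) does not reach a steady residual with this
  scheme — the two-phase cases of interest, whose effective viscosity is
  several times higher, converge; the single-phase verification cases use
  the unobstructed tube.
* First-order upwind is diffusive; the TVD deferred correction sharpens the
  study runs but slows convergence on fine grids.
* The $\phi$ transport clips at `phi_bounds`; clipped mass is logged and
  negligible in the shipped cases but the bound itself is a modelling
  choice.
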