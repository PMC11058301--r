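# hemoflow

Two-fluid finite-volume simulation of blood flow in microvessels.

## The problem

In arterioles (lumen diameters of tens to a few hundred micrometers) blood
cannot be treated as a homogeneous Newtonian liquid: red blood cells (RBCs)
occupy a large volume fraction, migrate across streamlines, deplete near
walls (the cell-free layer behind the Fåhræus–Lindqvist effect) and make the
suspension strongly shear-thinning. Tracking individual cells is hopeless at
these scales, so `hemoflow` treats blood as **two interpenetrating continua**
— Newtonian plasma and a non-Newtonian RBC phase — and solves their coupled
steady flow through idealized vessel geometries: a cosine-profile
axisymmetric **stenosis** and a planar **sudden-expansion** channel. The
quantities of clinical interest are the wall shear stress (WSS) along the
stenosed wall, the recirculation zone downstream of the constriction, and
the cell-free / cell-rich layers that form around it.

## The model

With φ the RBC volume fraction, shared pressure *p* and phase velocities
**v**ₚ (plasma), **v**ᵣ (RBC), the steady phase balances are

```
∇·[(1−φ) vp] = 0                     ∇·(φ vr) = 0
(1−φ)ρp (vp·∇)vp = ∇·Tp + (1−φ)ρp bp + fI
   φ ρr (vr·∇)vr = ∇·Tr +    φ ρr br − fI
```

with phase stresses

```
Tp = −p(1−φ) I + 2 μp (1−φ) Dp
Tr = −p φ I     + 2 μr φ Dr
```

The RBC viscosity is shear-thinning and hematocrit-dependent,

```
μr = ½ [ μ∞ + (μ0 − μ∞) (1 + ln(1+kγ̇)) / (1+kγ̇) ] (1+φ),    γ̇ = √(2 tr Dr²)
μ0(φ) = 537.002 φ² + 55.006 φ − 0.129   (cP)
μ∞(φ) =  27.873 φ² − 21.218 φ + 14.439  (cP),    k = 11 s
```

and the interphase momentum exchange combines hindered Stokes drag,
Saffman shear-lift and spin-lift:

```
fI = 9μp/(2a²) f(φ) (vr−vp)
   + 3(6.46)√(ρp μp)/(4πa) φ [2 tr Dp²]^(−1/4) Dp (vr−vp)
   + (3/4) ρp φ (Wr−Wp)(vr−vp),          f(φ) = φ(1 + 6.55 φ)
```

with plasma ρp = 1027 kg/m³, μp = 0.96 cP, RBC ρr = 1093 kg/m³ and RBC size
a = 8 µm. The discretization is a collocated finite-volume SIMPLE loop on
body-fitted structured grids (Rhie–Chow momentum interpolation, implicit
upwind / deferred-correction TVD convection, conservative implicit transport
of φ). See the methods vignette (`vignettes/two-fluid-microvessel.Rmd`) for
the numerics and all modelling choices.

## Worked example

The study's stenosis (H = 50 µm, hs = 25 µm, Ls = 70 µm) at inlet velocity
0.2 m/s and inlet hematocrit 20%:

```r
library(hemoflow)

geom <- stenosis_geometry()              # H = 50 um, hs = 25 um, Ls = 70 um
dimensionless_ratios(geom)
#> eta_h eta_L
#>   0.5   1.4

grid  <- build_stenosis_grid(geom, nx = 90, ny = 14,
                             cluster_wall = -1.2, cluster_throat = 2.5)
bc    <- boundary_conditions(inlet_velocity_Vt = 0.2, inlet_hematocrit_Ht = 0.2)
state <- steady_solve(grid, bc,
                      config = solver_config(max_outer = 400, tol = 2e-5,
                                             scheme = "tvd"))
state
#> <flow_state> 1260 cells, 172 outer iterations, converged
#>   final residuals: mom_p 1.87e-05 mom_r 1.92e-05 cont 3.53e-06 phi 2.62e-06

wp <- wall_shear_stress(state, grid)
max(wp$tau_wss)                          # 154.1 Pa ...
wp$x[which.max(wp$tau_wss)] * 1e6        # ... at x = -2.6 um (upstream of the throat)

recirculation_extent(state, grid) * 1e6
#>      x_sep x_reattach
#>   11.29973   58.00327
```

The WSS peaks *upstream* of the narrowest point, and a plasma recirculation
zone spans x ≈ 11–58 µm downstream of it. `layer_metrics(state, grid)`
locates the wall-adjacent cell-free region that coincides with that
recirculation (x ≈ 13–69 µm, up to 19 µm thick) and a small upstream
cell-rich accumulation — the qualitative structure the two-fluid model is
built to capture. `autoplot(wp)` and
`autoplot(section_profile(state, grid, 0))` plot the WSS profile and the
throat cross-section; `run_stenosis_sweep()` repeats the run over the inlet
velocity and hematocrit matrices and reports the monotonic trends, and
`run_expansion_validation()` runs the sudden-expansion benchmark with
gravity. A command-line wrapper lives at `inst/cli/hemoflow`
(`hemoflow run inst/extdata/stenosis_case.yaml --out results`).

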