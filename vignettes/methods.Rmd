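---
title: "Methods: stenosed jugular-vein flow with a flexible two-leaflet valve"
author: "ijvflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stenosed jugular-vein flow with a flexible two-leaflet valve}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ijvflow)
```

# The physical model

`ijvflow` simulates pulsatile blood flow through a planar (2D) model of the
internal jugular vein: a channel of length $L = 200$ mm and width
$D = 15$ mm.  Two features disturb the flow:

* **An upstream stenosis** — a nozzle-like contraction near the inlet that
  occludes a fraction $f$ of the width over a short axial span
  ($l_s = 5$ mm centred at $x_s = 20$ mm).  The open gap at the throat is
  $d_1 = (1-f)\,D$.  Four standard severities are studied:
  cases A–D with $f = 0,\ 0.30,\ 0.60,\ 0.75$.
* **A two-leaflet venous valve** downstream — two flexible hyperelastic
  flaps anchored on opposite walls at $x = 110$ mm, leaning downstream and
  leaving a resting tip gap $d_2 = 3$ mm.

The questions the model answers are qualitative and comparative: how do the
post-stenotic jet, the recirculation (reverse-flow) zones, the jet
asymmetry and the valve-leaflet deformation change as the stenosis
severity increases?

## Fluid

Blood is treated as an incompressible Newtonian fluid
($\rho = 1055$ kg/m$^3$, $\mu = 3.5$ mPa·s).  The solver is a
fractional-step (Chorin projection) scheme on a staggered marker-and-cell
grid: an explicit advection–diffusion predictor followed by a pressure
projection that enforces $\nabla\cdot u = 0$ to round-off.  The
pressure-Poisson operator — homogeneous Neumann at the inlet, walls and
masked solid cells, Dirichlet $p = 0$ at the outlet — is factorized once
per geometry with a sparse Cholesky decomposition (`Matrix`), so each step
costs two triangular solves.

The inlet carries the pulsatile waveform

$$U(t) = 8\,\sin(t\,\pi/6) + 12 \quad \text{cm/s},$$

a $16 \pm 4$ cm/s cycle that starts at 12 cm/s, peaks at 20 cm/s at
$t = 3$ s and returns to 12 cm/s at $t = 6$ s:

```{r waveform}
inlet_velocity(c(0, 1.5, 3, 6))  # cm/s
```

The stenosis is rasterized onto the grid as a mask of solid cells
(`wall_mask()`); masked cells take no-slip values and are excluded from
the pressure solve.

## Turbulence closure (optional)

At peak flow through a severe stenosis the throat Reynolds number reaches
a few thousand, so a Wilcox-type $k$–$\omega$ closure is available
(`turbulence = TRUE`).  The implementation uses the standard constants
$\alpha = 13/25$, $\beta_0 = 13/125$, $\beta_0^* = 9/100$,
$\sigma = \sigma^* = 1/2$, eddy viscosity $\mu_T = \rho k/\omega$, and the
cross-diffusion correction $f_{\beta^*}(\chi_k)$; the vortex-stretching
correction $f_\beta$ is identically 1 in 2D.  The sink terms are advanced
semi-implicitly, which makes the homogeneous-decay limit exact for
$\omega$ and accurate to $\sim 10^{-4}$ for $k$ at $\Delta t = 10^{-3}$ s,
and keeps both fields positive without ad-hoc clipping under normal
conditions (clipping events, if any, are counted and logged).

## Valve leaflets

The leaflet material is compressible neo-Hookean with strain-energy
density

$$W_s = \tfrac{\mu_s}{2}(I_1 - 3) - \mu_s \ln J + \tfrac{\lambda_s}{2}(\ln J)^2,$$

with Lamé constants derived from $E = 2.6$ MPa and $\nu = 0.3$:

```{r lame}
lame_from_modulus(E = 2.6e6, nu = 0.3)  # mu_s = 1.0 MPa, lambda_s = 1.5 MPa
```

`pk2_stress()` and `cauchy_stress()` implement the full finite-strain law
(plane strain), and reduce to linear elasticity at small strain — this is
one of the package's analytic validations.

Because each leaflet is long and thin ($10$ mm $\times$ 1 mm), its
dynamics are integrated as an **elastic fiber**: a chain of Lagrangian
nodes carrying the neo-Hookean small-strain moduli as stretching stiffness
$EA = E\,h$ and bending stiffness $EI = E\,h^3/12$ per unit depth, with a
clamped root (fixed anchor position and root tangent).  This
one-dimensional reduction preserves what matters at this scale — the
bending-dominated deflection of a thin flap — at a small fraction of the
cost of a 2D finite-element membrane; the fiber's first natural frequency
converges to the Euler–Bernoulli value as the node count grows
(also under test).

## Fluid–structure coupling

The leaflets are coupled to the fluid with a regularized-delta
immersed-boundary method (4-point kernel).  Velocity is interpolated to
the nodes and force is spread back with the *same* kernel, so
interpolation and spreading are discrete adjoints and the kernel weights
are a partition of unity — both properties are enforced by tests at
$10^{-10}$/$10^{-12}$ tolerance.

The structural step is a **linearized backward-Euler solve**: one
$2n \times 2n$ linear system per leaflet per time step, built from the
analytic stretch and bending tangents plus an implicit velocity-matching
drag of strength

$$c_v = \texttt{ib\_penalty} \cdot \rho\, h_x h_y / \Delta t .$$

The reaction impulse is spread back to the fluid before the projection.
Treating the drag implicitly inside the structural solve is what keeps the
light, stiff leaflets stable at the fluid's CFL time step — an explicit
penalty coupling of this leaflet (mass ratio $\sim 1$) is unconditionally
unstable in practice (the classical added-mass effect).
`ib_penalty = 0.3` (default) sets how strongly the leaflet is dragged
toward the local fluid velocity per step; values in $[0.1, 1]$ behave
similarly, with larger values stiffening the coupling.

# Numerical parameters that matter

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `cfl` | 0.4 | – | advective CFL fraction; the step also respects a diffusive limit and `dt_max` |
| `dt_max` | $2\times10^{-3}$ | s | cap on the time step |
| `ib_penalty` | 0.3 | – | immersed-boundary velocity-coupling strength |
| `damping` | 0 | 1/s | optional structural damping |
| `turb_intensity`, `turb_length` | 0.05, 0.0015 | –, m | inlet $k$–$\omega$ boundary values |
| `perturb` | 0 (presets: 0.02) | – | RMS antisymmetric inlet tilt (see below) |

Two presets bundle these with problem sizes:

* **`"desk"`** — $200\times16$ cells, 3 s simulated, laminar.  This is the
  package's own working scale: every qualitative phenomenon of interest
  (jet, separation, asymmetry, leaflet deflection) is present, and a full
  case runs in under a minute.
* **`"paper"`** — $400\times30$ cells, 6 s (one full inlet cycle),
  $k$–$\omega$ closure on.

## The inlet perturbation (`perturb`)

A perfectly symmetric discretization of a perfectly symmetric channel
stays mirror-symmetric to round-off, which artificially suppresses the
antisymmetric (jet-flapping) instability that any real vessel exhibits —
real flows are seeded by geometric and physiological asymmetries that the
idealized model lacks.  The presets therefore apply a small random
antisymmetric tilt to the inlet profile each step:

```r
tilt <- 2 * yc / D - 1                      # -1 at one wall, +1 at the other
U_in <- U_in * (1 + perturb * rnorm(1) * tilt)
```

The tilt has exactly zero net flux (mass inflow is unchanged) and RMS
amplitude `perturb` (2% in the presets).  Runs remain deterministic given
the configuration, because the seed is part of `sim_control()` and is
recorded in the provenance.  With `perturb = 0` the solver is fully
deterministic and symmetric cases remain symmetric.

## Disturbance metrics and their thresholds

All metrics live in one place and carry fixed, pre-declared definitions:

* **Per-section maximum velocity** `max_velocity_vs_x()`: the along-vessel
  profile $\max_y |u|(x)$; `run_case()` also accumulates its time average
  over the last third of the run (`profile_mean`).
* **Reverse-flow area** `reverse_flow_area()`: total area of
  4-connected regions with axial velocity below $-\varepsilon$, with
  $\varepsilon = 10^{-3} \cdot \max|u|$.  The region of interest is
  *downstream of the stenosis and upstream of the valve anchor*.  A case
  counts as having "near-zero" separation when this area is below **5%**
  of the region-of-interest lumen area.
* **Post-throat dip** `post_throat_dip()`: $1 - \min/\max$ of the
  time-averaged profile over a 30 mm window just downstream of the throat
  versus the throat itself.  A dip deeper than **10%** marks the jet
  breakdown/recirculation signature of severe stenosis.
* **Jet asymmetry** `asymmetry_index()`: the odd-about-the-midline energy
  fraction of the axial-velocity field (0 = mirror symmetric,
  1 = perfectly antisymmetric).
* **Leaflet asymmetry** `leaflet_asymmetry()`: difference of the two
  leaflet-tip displacement magnitudes.

Time averages use the last third of the run, skipping the initial
transient.  The 5% and 10% thresholds were fixed before the comparative
runs were made and are deliberately coarse: the phenomena they detect
differ by an order of magnitude between mild and severe stenosis.

# A complete example

```{r example, eval = FALSE}
ctrl <- preset_control("desk")
cases <- standard_cases(control = ctrl)
runs <- lapply(cases, run_case)          # ~40-60 s per case
compare_cases(runs)
```

A representative comparison table (desk preset, seed 1):

```
 case    f throat_peak reverse_area asymmetry leaflet_asym peak_rank
    A 0.00       0.240      1.9e-06   0.00126      1.3e-05         1
    B 0.30       0.314      5.1e-05   0.00242      8.2e-05         2
    C 0.60       0.729      4.9e-04   0.645        2.5e-04         3
    D 0.75       1.082      4.8e-04   0.663        3.2e-04         4
```

The qualitative picture: mild stenosis (B) accelerates the jet but the
flow reattaches almost immediately; severe stenosis (C, D) produces large
recirculation zones, a velocity dip just downstream of the throat, a
strongly asymmetric flapping jet, and visibly asymmetric valve-leaflet
bending.

Grid independence is checked with the built-in ladder utility:

```{r mesh, eval = FALSE}
mesh_independence(config, list(c(100, 8), c(200, 16), c(400, 32)))
```

# What the model does and does not show

The model is a deliberate idealization, and its tests certify the
*numerics*, not clinical fidelity:

* It is 2D: out-of-plane vortex stretching, secondary flows and realistic
  3D valve geometry are absent.
* Blood is Newtonian here; shear-thinning matters in the low-shear
  recirculation zones.
* The vessel wall is rigid except for the leaflets; venous compliance and
  collapse are not modeled.
* The stenosis is a clean geometric contraction, not patient morphology.
* The inlet perturbation is a surrogate for unresolved asymmetries; its
  amplitude (2%) sets how fast the flapping instability is seeded, not
  whether it exists.

Within that scope, the analytic validations (Poiseuille profile, Lamé
conversion, small-strain constitutive limit, $k$–$\omega$ decay,
projection/adjointness contracts, grid convergence) pin every numerical
component to a closed-form oracle, and the comparative properties of the
four stenosis cases are reproduced at desk scale.
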