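---
title: "Methods: a lattice Boltzmann model for particle focusing in viscoelastic microchannel flow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: viscoelastic LBM with immersed membrane particles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The physical problem

A rigid spherical particle suspended in a dilute polymer solution and
driven through a straight microchannel migrates across streamlines: the
first normal stress difference $N_1 = \tau_{xx} - \tau_{nn}$ of the
viscoelastic fluid pushes it toward low-shear regions, while inertial
lift pushes it away from walls and away from the centreline. The balance
is controlled by the Reynolds number $Re = \rho U L / \eta_t$, the
Weissenberg number $Wi = \lambda_p U / L$ and their ratio, the
elasticity number $El = Wi/Re$, with $L = 2hw/(h+w)$ the characteristic
length of an $h \times w$ rectangular cross-section. Depending on $El$,
the channel aspect ratio $AR = h/w$ and the blockage $d/h$, particles
focus on the centreline, at corners, on off-centre lines, or spread over
the long mid-plane — the effects exploited by microfluidic cell-focusing
and size-based sorting devices. `viscolbm` implements a
three-dimensional solver for exactly this system and the analytic
fixtures needed to validate it.

## Model and discretisation

**Solvent.** The incompressible Navier–Stokes equations with solvent
viscosity $\eta_s$, polymer stress divergence $\nabla\cdot\tau$ and
driving body force are solved with a single-relaxation-time (LBGK)
D3Q19 lattice Boltzmann scheme,

$$f_\alpha(x + c_\alpha, t+1) = f_\alpha + \tfrac{1}{\lambda}(f^{eq}_\alpha - f_\alpha) + F_\alpha,$$

with the standard second-order equilibrium, Guo's forcing term
$F_\alpha$ and the half-force velocity correction
$\rho u = \sum_\alpha c_\alpha f_\alpha + F/2$. The relaxation time
fixes the solvent viscosity, $\nu_s = (\lambda - 1/2)/3$ in lattice
units.

**Polymer stress.** The Oldroyd-B constitutive equation

$$\lambda_p \frac{D\tau}{Dt} = \tilde\nu \nabla^2 \tau +
  \lambda_p\left(\tau\cdot\nabla u + (\nabla u)^T\cdot\tau\right)
  - \tau + 2\eta_p d$$

is evolved with a second D3Q19 distribution $G_{ij\alpha}$ per
independent stress component, relaxing toward an advected equilibrium
$G^{eq}_{ij\alpha} = \omega_\alpha \tau_{ij}[1 + 3c_\alpha\cdot u + \dots]$
and forced by the source
$\chi = \tau\cdot\nabla u + (\nabla u)^T\cdot\tau +
(2\eta_p d - \tau)/\lambda_p$, direction-weighted with the
$(\tilde\lambda - 1/2)/\tilde\lambda$ velocity correction. The stress is
recovered as $\tau_{ij} = \sum_\alpha G_{ij\alpha}$, and its divergence
enters the solvent as the elastic body force $F_V = \nabla\cdot\tau$.
Only the six independent components of the symmetric tensor are stored
and evolved (a 3x3 view is mirrored on demand); symmetry is therefore
exact by construction. The time derivative $\partial_t\chi$ in the
update is a first-order backward difference using the cached source of
the previous step — the term is already $O(\Delta t^2)$, so only local
history is needed.

**Particles.** A particle is a closed triangulated shell: 120 faces for
the 6 µm preset (the barycentric subdivision of the icosahedron — the
unique standard near-uniform family hitting 120 and, after one midpoint
refinement, 480 faces for the 12 µm preset), projected onto the sphere.
Its deformation energy is $E = E_S + E_B + E_A + E_V$: a per-face
strain law $\kappa_S(I_1^2 + 2I_1 - 2I_2)/12 + \kappa_\alpha I_2^2/12$
in the stretch invariants, a dihedral-angle bending sum over the $3N/2$
edges, and global quadratic area and volume penalties. Nodal forces are
the exact analytic gradient $f(x_n) = -\partial E/\partial x_n$
(validated against central finite differences in the test suite).
With the rigid preset moduli ($\kappa_S = \kappa_\alpha = 0.32$ N/m,
$\kappa_B = 3.2\times10^{-13}$ N·m, $\kappa_A = 3.2\times10^{-2}$ N/m,
$\kappa_V = 3.2\times10^{4}$ N/m²) the shell deforms by well under a
percent of its diameter and behaves as a rigid sphere; no explicit
rigid-body solver exists.

**Coupling.** The immersed boundary method with the 4-point cosine
kernel $\delta(r) = (1 + \cos(\pi r/2))/4$ spreads nodal forces onto the
lattice and interpolates lattice velocities back (the same kernel both
ways, so the total force handed to the fluid equals the total membrane
force to machine precision). Nodes advance by forward Euler.

## Units and parameter interpretation

Internally everything is in lattice units ($\Delta x = \Delta t = \rho_0
= 1$); the configuration block is SI and converted once at setup.
With the published parameter set ($\Delta x = 10^{-6}$ m, $\Delta t =
10^{-7}$ s, $\nu = 10^{-6}$ m²/s) the relaxation time is $\lambda = 1/2 +
3\nu\Delta t/\Delta x^2 = 0.8$.

One interpretation had to be fixed: a single kinematic viscosity
$\nu = 10^{-6}$ m²/s appears both in the LBGK viscosity relation and in
the driving-force calibration, while $Re$ and $Wi$ are defined with the
*total* viscosity and the constitutive law requires the f-lattice to
carry only the *solvent* viscosity. These cannot all refer to the same
number. `viscolbm` takes the config `nu` to be the solvent kinematic
viscosity (the quantity the LBGK relation actually controls, preserving
$\lambda = 0.8$), sets $\nu_t = \nu/\beta$, and calibrates the driving
acceleration with the total viscosity, $a = 32\nu_t^2 Re/L^3$, so that
the nominal $Re$ is achieved exactly for a circular pipe. For
rectangular ducts the circular-pipe formula under-drives the flow, so
every run re-measures $Re$, $Wi$ and $El$ from the simulated mean
velocity and reports both nominal and measured values. The fluid
density, which the reference parameter set leaves open, is taken as water
(1000 kg/m³); it only enters the conversion of the membrane moduli, and
particles are neutrally buoyant (no gravity term).

## Boundaries

Walls are **on-lattice**: wall nodes sit on the physical boundary and
their populations are set by non-equilibrium extrapolation,
$f_\alpha(x_w) = f^{eq}_\alpha(\rho_f, u_w) + [f_\alpha(x_f) -
f^{eq}_\alpha(x_f)]$, from a designated adjacent fluid node (inward
normal for wall faces, the interior diagonal for corners), and the same
construction applies to $G_{ij\alpha}$ with the neighbour's stress. The
half-spacing (mid-link) wall placement was considered and rejected: the
extrapolation scheme is formulated for on-node walls, and on-node
placement keeps the wall velocity exact in the velocity-gradient
stencils.

Two finite-difference conventions follow from this choice:

* **velocity** gradients use central differences *through* wall nodes,
  because the wall node carries the exact no-slip velocity;
* **stress** derivatives (for $F_V = \nabla\cdot\tau$) use fluid values
  only, with one-sided second-order stencils at wall-adjacent nodes,
  because the extrapolated wall stress is a zeroth-order copy of its
  fluid neighbour. Differencing through it flattens the near-wall
  stress gradient and measurably removes polymer wall drag.

**Circular masks.** The tube cross-section is a staircase: fluid nodes
with $r < R_{mask}$, a closed wall layer of non-fluid nodes touching
fluid through any stencil link, inactive nodes beyond. On the symmetry
axes the wall nodes sit at $R_{mask} + 0.5$, and the simulated
centre-plane profile is parabolic with that radius to a fraction of a
percent; the *flow rate*, however, reflects the azimuthally averaged
staircase radius, which is a little smaller and approaches
$R_{mask} + 0.5$ only as the resolution grows. The acceptance test for
the Newtonian tube therefore checks the profile shape (normalised by
the centreline value) at 2% and the absolute amplitude at 5%; both
margins are resolution-limited geometry, not scheme error.

## Numerical choices

* **Tensor-lattice relaxation $\tilde\lambda$ (default 0.505).** The
  G-lattice adds an artificial stress diffusivity $\tilde\nu =
  (\tilde\lambda - 1/2)/3$ that stabilises sharp stress gradients. The
  natural-looking 0.55 proved far too diffusive at desk resolutions: the
  stress boundary layer $\sqrt{\tilde\nu\lambda_p}$ spans ~2.6 lattice
  spacings on a 21-node tube at $Wi = 0.3$ and corrupts $\tau_{xx}$ by
  over 20%. The default 0.505 keeps that layer below one spacing and
  brings the tube validation within 3%; the parameter remains
  configurable.
* **Step order.** Per step: stress recovery, moments, total force
  (driving + $\nabla\cdot\tau$ + spread membrane forces), half-force
  velocity, velocity gradient and constitutive source, fused
  collide-and-stream of both lattices with the wall extrapolation, then
  IBM interpolation and node advection. Nodes are advected with the
  **post-update** velocity: with the pre-update velocity the restoring
  force a node exerts reaches it one step late, and that lag
  destabilises stiff membranes once the particle translates across grid
  cells.
* **Node positions are stored unwrapped** along the periodic flow axis.
  Wrapping nodes individually would tear the connected mesh at the
  seam; the interpolation/spreading kernel wraps coordinates onto the
  lattice instead. Trajectories report the unwrapped axial position.
* **No membrane sub-stepping.** A sub-stepping knob was considered and
  dropped: nodes move with the interpolated fluid velocity, so the
  stiff elastic forces enter the dynamics only through spreading, and
  sub-dividing the membrane update without sub-dividing the fluid step
  changes nothing.
* **Initialisation.** Channels start from rest at unit density with
  zero polymer stress; the shear-box fixture can optionally start from
  the developed Couette state (linear profile plus the uniform steady
  simple-shear stress, which is an exact fixed point of the
  constitutive update), cutting the start-up transient from
  $\mathrm{gap}^2/\nu$ steps to the particle spin-up time.
* **Subsonic guards.** A warning above $|u| = 0.1c$, an abort above
  $0.3c$; LBGK is only weakly compressible.
* **Checkpoints** are RDS (no HDF5 bindings are available in the target
  environment); they hold every population of both lattices, the cached
  source tensor and the particle nodes, and resuming is bit-identical
  to an uninterrupted run — the method has no stochastic element.

## What the scaled-down validations establish (and what not)

The published trajectory maps integrate 1,200,000 steps on 40–50 µm
cross-sections — cluster-scale work. The test suite instead runs:

* analytic-oracle agreement (tube Poiseuille for Newtonian and
  Oldroyd-B flow, Couette stress, rotation rate $\gamma\dot{}/2$ of a
  sphere in Newtonian shear) at a few percent on coarse lattices;
* property suites (conservation laws, gradient oracles, symmetry,
  determinism) at machine precision;
* *qualitative* reproductions on a ~24-node cross-section over a few
  $10^4$ steps: a particle released mid-sector at low $El$ moves toward
  the centreline (a signed-displacement test), and the rotation rate of
  a sphere in viscoelastic shear decreases monotonically across
  $Wi \in \{0.5, 1.5, 3\}$.

A green qualitative test shows the migration *direction* and *ordering*
are right at desk scale with a blockage ratio ($d/h = 0.25$) larger
than published; it does not reproduce equilibrium positions,
separatrices or focusing times, which need the full resolution and
horizon. Note that at this blockage a particle released far out at
(−0.4, −0.2) migrates toward the corner — consistent with the published
observation that the separatrix shrinks for larger particles — so the
sign test deliberately starts well inside the separatrix.

## Known limitations

* Single particle per run; no particle–particle lubrication or contact.
* Constant-viscosity Oldroyd-B only (no shear-thinning Giesekus/PTT).
* Staircase tube walls limit absolute amplitude calibration to a few
  percent at 21-node resolution (see above).
* The explicit membrane coupling restricts the product of moduli and
  local velocity scale; the published moduli are stable at the
  published velocity scales, but substantially stiffer particles or
  faster flows would need smaller time steps than the fixed
  $\Delta t$ calibration provides.
* Literature comparison curves for the rotation-rate validation are out
  of scope (the reference datasets are not available in tabulated form).
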