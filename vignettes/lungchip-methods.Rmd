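---
title: "Methods: flow, particle dynamics and transport metrics in lungchip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: flow, particle dynamics and transport metrics in lungchip}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`lungchip` simulates the transport of inhaled nanoparticles in a dual-channel
lung-on-a-chip: an air channel stacked on a cell-culture media channel,
separated by a thin membrane perforated by regularly spaced pores. This
vignette documents the model, its assumptions, the numerical choices and the
design decisions that were genuinely open, in enough detail to judge what a
passing test suite does and does not demonstrate.

## Geometry and coordinate conventions

The device is modeled in 2D (the channel cross-stream plane `x`–`y`, unit
out-of-plane depth). `y = 0` is the media-channel floor; the membrane occupies
`[h_media, h_media + b]`; the air channel sits above it; gravity points along
`−y`, from air toward media. Defaults follow the common device scale:
channel heights `h_air = h_media = 100 µm`, length `l = 2 mm`, membrane
thickness `b = 10 µm`, pore widths `d = 10` or `3 µm` with edge-to-edge
spacings `p2p = 10` or `5 µm`.

Two conventions had to be fixed because device descriptions rarely state
them:

* **Pore tiling.** Pores tile the perforated extent (default: the full
  channel overlap `[0, l]`) left to right with period `d + p2p`,
  interpreting `p2p` as edge-to-edge spacing. For the default geometry this
  yields 100 pore slots and an open-area fraction `d/(d + p2p) = 0.5`.
* **2D pores.** A pore is a through-slot of width `d` spanning the membrane
  thickness — the planar analogue of a cylindrical pore. Open-area fraction,
  not pore shape, is the quantity this 2D model can match.

## Flow model

Both phases are Newtonian and incompressible; at the operating points the
channel Reynolds numbers are at most ~0.14 (media, 1 mm/s), so the solver
drops the convective term and solves the steady Stokes problem

\[ \nabla\cdot u = 0, \qquad 0 = -\nabla p + \mu \nabla^2 u , \]

with phase-local density and viscosity (air at 37 °C: `1.123 kg/m³`,
`0.019 mPa·s`; media: water-like at 37 °C, `1000 kg/m³`, `0.718 mPa·s`).
Boundary conditions: prescribed inlet velocity (uniform plug by default; a
fully developed parabolic option exists because the parallel-plate
verification cases assume it), zero outlet pressure, no-slip on every solid
boundary. Dropping the convective term makes the field exactly linear in the
inlet velocities, which the test suite asserts. The continuum treatment of
the airflow is justified by the channel Knudsen number
`Kn = k_B/(√2 π σ² ρ_a R · 2h) ≈ 4×10⁻⁴ < 0.01` (hard-sphere collision
model, σ = 346 pm, R ≈ 290 J/(kg·K)).

**Gravity in the flow.** The hydrostatic body force `ρ g` is absorbed into a
reduced pressure and omitted by default: within each constant-density phase
it is dynamically inert, and retaining it across two stacked phases of very
different density would impose an artificial transmembrane head that no
closed microdevice sustains. A flag (`include_gravity`) restores it.

**Pore flow: the one genuinely consequential design decision.** If the two
channels are solved as one connected fluid domain (`pore_flow = "open"`),
the media channel's much larger axial pressure drop (~0.5 Pa vs ~0.01 Pa in
air) drives most of the media inflow up through the pore slots — in the
default device about 90% of it short-circuits into the air channel, with
upward pore velocities of order `3×10⁻⁵ m/s`, comparable to the settling
velocity of a 900 nm particle. A real gas–liquid device does not behave this
way: the liquid–air menisci pinned in the pores sustain capillary pressures
of order `2σ/d ≈ 10⁴ Pa`, four orders of magnitude above the available
head, so no fluid is exchanged. The default is therefore
`pore_flow = "closed"`: the slots hold stagnant liquid in the flow solve
(each channel keeps its own flow), while remaining fully passable for
particles. The connected solve is retained as an option and is exercised by
the symmetry test (identical fluids and equal inlets must produce zero net
pore flux).

**Phase of the pore interior.** Particles inside a slot experience the
bottom-phase (liquid) properties: the membrane of a gas–liquid device is
wetted from below, so the slot interior is liquid. A particle's *status*
still changes from air to media only when it exits a slot into the bottom
channel, which is when its translocation time is recorded.

**Shallow-channel drag.** A finite out-of-plane depth can be approximated by
the depth-averaged Hele-Shaw body force `−12 μ u / depth²`. Its intended use
is the verification that deposition is insensitive to the out-of-plane
depth, which the suite checks by comparing a 2 mm depth against the
unbounded default.

### Discretization and linear solver

Uniform staggered (MAC) grid: `u` on vertical faces, `v` on horizontal
faces, `p` at cell centers; second-order centered viscous terms with
symmetric face/edge viscosity averages at phase interfaces; no-slip enters
through mirror ghosts where walls coincide with cell edges. The cell size
defaults to `d/6` — at least six cells across each pore — and the channel
heights and membrane thickness must be integer multiples of it (checked;
the default geometry is exactly commensurate). The default device meshes to
1200 × 126 cells (~4.5×10⁵ unknowns).

The discrete Stokes system is solved exactly (to an iterative tolerance):
the viscous block `K` is symmetric positive definite and factored once with
a supernodal sparse Cholesky; conjugate gradients then solve the pressure
Schur complement `Gᵀ K⁻¹ G p = Gᵀ K⁻¹ f + g`, preconditioned by the
viscosity-scaled pressure diagonal, to a relative residual of `1e-10`. The
38-fold air/media viscosity contrast costs iterations (the air block's
pressures are ~40× smaller, so the global tolerance forces extra reduction
there; ~600 iterations for the default device, ~30 for a single phase) but
each iteration is only two triangular solves. An approximate-Schur
(`Gᵀ diag(K)⁻¹ G`) preconditioner was evaluated and converged *slower* on
these geometries; the mass diagonal was kept. Convergence diagnostics
(iterations, relative residual, maximum discrete divergence) are stored on
every field; the suite requires the divergence to be at the solver floor and
the per-channel flux balance (inlet = outlet + pore exchange) to close.

Velocity sampling for the tracer is bilinear on the staggered lattice with
mirror-ghost padding, so nodal values are reproduced exactly and the
interpolant vanishes on walls that coincide with cell edges.

## Particle dynamics

Each particle obeys

\[ m_p \frac{du_p}{dt} = 3\pi\mu d_p (u - u_p) + \zeta\sqrt{6\pi k_B \mu T d_p/\Delta t} + m_p\Big(1-\frac{\rho_i}{\rho_p}\Big) g , \]

with `ζ` standard normal per component and per step, `T = 310.15 K` in both
phases, and one-way coupling only (the particle volume fraction is far too
small to act back on the flow; inertial lift, particle–particle interactions
and electrostatics are neglected). Cunningham slip correction is omitted by
default for strict Stokes drag; it matters at the 10 nm end and can be
revisited by scaling the drag, but the package keeps the uncorrected law as
its reference physics.

Two integrators:

* **Overdamped (default, `d_p ≤ ~1 µm`).** The relaxation time
  `τ = ρ_p d_p²/18μ` is at most `10⁻⁷ s` for submicron particles in either
  phase — many orders below any resolvable step — so the position-Langevin
  limit is exact for practical purposes:
  `x ← x + (u + v_s ê_g) Δt + √(2DΔt) ζ`, with settling velocity
  `v_s = (ρ_p − ρ_i) g d_p²/18μ` and Stokes–Einstein diffusivity
  `D = k_B T/3πμ d_p`. The Brownian displacement reproduces exactly the
  per-step variance obtained by pushing the Brownian force through the drag
  law.
* **Inertial.** The exact exponential update of the linear drag ODE over
  one step (unconditionally stable for any `Δt/τ`), with gravity and the
  Brownian force held piecewise constant. Used for validation (it matches
  the analytic relaxation to machine precision) and for micron-scale beads.
  The suite checks that both integrators agree on deposition and transfer
  within Monte-Carlo error for 900 nm particles.

**Time step.** Chosen so that both the advective sub-step (peak fluid speed
plus settling) and the r.m.s. Brownian sub-step stay below a quarter of the
smallest boundary feature (`min(d, b)/4`; a tenth of the channel height for
impermeable membranes). This bounds the chance of stepping across a pore or
the membrane without classifying the crossing.

**Boundaries.** Motion is resolved event-by-event along each step segment:
the membrane top is sticky (particles freeze at the exact crossing point;
its `x` is the deposit record); pore mouths pass particles through; a
particle leaving a slot into the bottom channel switches to the media phase
and logs its transfer time; crossing the outlet plane records exit time and
(for the media channel) the interpolated exit height; every other wall —
channel ceiling, floors, slot side walls, membrane underside, the inlet
plane — reflects specularly. The membrane underside reflects even at pore
mouths, making translocation one-way; a real particle could in principle
diffuse back up a pore, but for the particle sizes and time horizons
simulated the backflux through a 10 µm mouth against settling is negligible,
and the one-way rule keeps the fate ledger a clean partition.

**Randomness.** Every particle derives an independent counter-based stream
(splitmix64-hashed `(seed, particle, step, draw)` counters, Box–Muller
normals) from the master seed. Results are therefore bit-reproducible and
independent of scheduling or ensemble size: particle 7 of a 10-particle run
and particle 7 of a 1000-particle run follow identical trajectories.

**Injection.** Default release is uniform over the air-inlet height at
`x = 0`, with initial velocity equal to the local fluid velocity (an
"initially inert" zero-velocity option exists). The ensemble size default of
1000 keeps the binomial standard error of a rate estimate below ~1.6%.

## Transport metrics

* **Deposition rate** ε = deposits / released; **transfer rate** =
  translocations / released. For complete runs
  ε + transfer + air-outlet fraction = 1.
* **Distribution statistics** are population moments of normalized
  positions: deposit `x/l` along the substrate, exit `y/h_media` at the
  media outlet (floor = 0, membrane side = 1, so accumulation under the
  membrane reads high). The ideal uniform references are mean 1/2 and
  standard deviation `1/√12 ≈ 0.289`; population (not sample) moments are
  used so a lone deposit has zero spread.
* **Band concentration** partitions `[0, l]` into equal bands and divides
  per-band counts by the band measure (band length × channel height, unit
  depth) and a reference areal concentration `C0 = 10⁵ m⁻²`; the axis is
  normalized by the convective–diffusive decay length `3hPe/16`,
  `Pe = 2ūh/D`.
* **Concentration–time curve**: the cumulative fraction of released
  particles that has left the media outlet, on 200 uniform time bins
  spanning the observed exits (stable central differencing needs a fixed
  grid; the bin count is a smoothing choice, not physics), differentiated
  and fitted with `A·exp(−(t−t₀)²/2w²)` by Levenberg–Marquardt least
  squares initialized from the raw peak. `cmax = A`, `tmax = t₀`; the area
  under the rate curve equals the realized transfer. Fewer than five exits
  skip the fit and flag the curve.

## Verification suite

`verification_suite()` runs four limiting-case batteries with the membrane
sealed (`d = 0`):

1. **Analytic profile.** The numerical cross-channel profile far from the
   inlet must match plane Poiseuille within 1%.
2. **Band-concentration decay.** A diffusing ensemble released across the
   inlet of a 1 mm × 20 mm channel must show monotone band-concentration
   decay and full mass accounting. The mean velocity is chosen so the decay
   length `3hPe/16` sits at half the channel length — the dimensionless
   problem is preserved while the decay completes inside the simulated
   domain; at the device's own Péclet numbers the decay length would be
   hundreds of meters and nothing measurable would happen within the
   channel.
3. **Depth independence.** Deposition with the shallow-channel term at 2 mm
   depth must agree with the unbounded-depth run within Monte-Carlo error.
4. **Settling regimes in water.** Micron-scale bead twins of a bench
   experiment: 1 µm / 2200 kg/m³ beads at 0.3 mm/s in a 100 µm channel wash
   out without depositing; 10 µm / 1470 kg/m³ beads at 0.1 mm/s in a 300 µm
   channel deposit almost completely, concentrated at the entrance; tripling
   the velocity spreads the deposit downstream. The bench bolus was
   accumulated at the inlet and injected all at once, but its vertical
   profile was not recorded; the twins release the bolus over the upper part
   of the inlet (`0.6h`–`0.9h`). This is the one free choice in the battery:
   a mid-height or full-height release would place part of the bolus below
   the advection–settling separatrix (a particle released at height `y₀`
   travels `(6ū/v_s h²)(h y₀²/2 − y₀³/3)` before grounding) and produce
   deposition that the bench observation rules out. The release band is
   configurable.

## Problem sizes and runtime

The shipped tests and the acceptance script use the default grid (six cells
per pore; 1200 × 126 for the full device, ~30 s per solve, cached per
geometry/velocity pair) and ensembles of 400–1000 particles per case
(2000–10⁴ for the pure-diffusion oracles), sizes at which every qualitative
comparison in the suite is resolved at 95% Monte-Carlo confidence while the
whole battery stays interactive. Production studies can raise both knobs;
rate estimates converge as `n⁻¹/²` and the flow solve is exact at any grid,
so only boundary-classification fidelity (cells per pore) warrants grid
refinement; in a spot check doubling the resolution to twelve cells per pore
moved deposition and transfer rates by no more than ~1.5 Monte-Carlo
standard errors of an 800-particle ensemble.

## What the simulations do and do not show

The model reproduces the transport physics of an idealized device: steady
laminar single-phase flows, rigid geometry, clean spherical particles, no
cell layers. Passing tests demonstrate correct creeping-flow hydrodynamics,
correct Langevin statistics and boundary bookkeeping, and the qualitative
parameter trends that follow from them (diffusion-dominated deposition below
~100 nm, settling-dominated above ~200 nm, porosity-controlled
translocation, velocity-controlled washout). They do not speak to: cell
uptake or surface chemistry (a sticky wall is a perfect absorber), membrane
stretching or breathing actuation, hygroscopic growth or agglomeration,
3D secondary flows near pore edges, slip-corrected drag at the smallest
sizes, or two-way momentum coupling at high particle loadings.
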