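---
title: "Modelling tissue-scale ciliary transport and mixing"
author: "ciliaflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling tissue-scale ciliary transport and mixing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ciliaflow)
```

## The model

Airway-lining epithelial cells carry beating cilia whose coordinated
motion propels the overlying mucus and everything trapped in it.  The
package simulates an idealized version of this system on a tissue-scale
patch: a Newtonian fluid at zero Reynolds number above a rigid no-slip
plane (the cell surface, `z = 0`), driven by prescribed rigid-rod cilia,
with passive massless tracers standing in for transported particles.

The three ingredients are:

1. **Beat kinematics.**  Each cilium is a rigid rod anchored at a point
   `x0` on the wall.  It rotates counter-clockwise about the vertical at
   angular velocity `omega` (`36*pi` rad/s, i.e. 18 Hz), so the azimuth
   is `phi(t) = phi0 + omega*t`.  Its length is `L = 7` um throughout
   the effective stroke (`phi` in `[0, pi]`) and follows a printed cubic
   contraction during recovery (minimum about 5.2 um), which encodes the
   biological power/recovery asymmetry: a straight, extended cilium
   sweeping one way, a shortened one returning.  The polar angle
   `theta(phi)` is confined to `[0.8, 2.4]` radians.  A node at fraction
   `sigma` of the length sits at
   `x0 + sigma * L(phi) * (cos(theta)cos(phi), cos(theta)sin(phi), sin(theta))`
   and its velocity is the exact time derivative, including the
   shortening term along the rod axis.

2. **Stokes flow with an exact wall.**  Force is spread along each rod
   at 15 nodes using the regularized-Stokeslet blob
   `psi_eps(r) = 15 eps^4 / (8 pi (r^2 + eps^2)^(7/2))`, `eps = 0.1` um
   (the cilium thickness).  The free-space velocity of one regularized
   Stokeslet is `8 pi mu u = f H1(r) + (f.y) y H2(r)` with
   `H1 = (r^2 + 2 eps^2)/(r^2 + eps^2)^(3/2)` and
   `H2 = (r^2 + eps^2)^(-3/2)`.  The no-slip condition on `z = 0` is
   enforced by an image system derived by convolving the classical
   singular image solution for a point force over a plane wall with the
   blob; the blob's vertical moments have closed forms, so the image
   reduces to four compact radial coefficient functions (documented in
   `src/kernels.cpp`).  The resulting field vanishes identically on the
   wall (machine precision), is divergence-free, and matches the
   singular image solution at separations large compared with `eps`.

3. **Tracer advection.**  Massless tracers follow `dx/dt = u(x, t)`
   under classical RK4, with the rod phases advanced consistently at
   substage times.  Boundaries are open: tracers may drift out of the
   patch and are not re-injected.  Because the wall-bounded flow
   vanishes at `z = 0`, tracers cannot cross the wall.

## The polar-angle law

Only the range `[0.8, 2.4]` of `theta` is constrained by the
experimental literature on tracheal beat patterns; the interpolation in
phase is a modelling choice, and it matters.  The package's default is
the pi-periodic law

`theta(phi) = 0.8 + 1.6 * (1 - cos(2 phi)) / 2`,

under which the rod arcs over the top once per half-revolution: the
extended effective rod does its work high above the wall while the
shortened recovery rod sweeps back low, close to the wall where the
image system suppresses its far field.  That height-times-force
asymmetry is what pumps fluid in the direction of the effective stroke
(negative x) and drives the slow upward drift of tracers.  The
2-pi-periodic alternative `theta = 0.8 + 1.6 (1 - cos phi)/2`
(`theta_shape = "cosine"`), which pins the range endpoints to the stroke
switches, makes the two strokes height-symmetric; in simulation its net
clearance is weak and can even point the wrong way, because the only
remaining asymmetry is the length law.  Note that any continuous law
with `theta(0) = 0.8` and `theta(pi) = 2.4` is forced into this
symmetric trap: the recovery stroke must retrace the same polar
interval, so it cannot hug the wall.  Both laws (and a triangle-wave
variant) are available through `beat_law(theta_shape = ...)`; all
results in this vignette and in the test suite use the default unless
stated.

## Forcing: resistive versus mobility

The force coefficient on each node is updated from the node's
prescribed velocity.  Two modes are provided:

* **resistive**: `f_i = gamma * v_i`.  The scalar `gamma` is
  calibrated once per configuration so that the fluid speed evaluated
  at an isolated rod's tip at mid effective stroke equals the
  prescribed tip speed (`calibrate_gamma()`, about 1.06 at the
  defaults).  This pins the overall velocity scale to the cilium's own
  speed; Stokes linearity means `gamma` otherwise only rescales time.
* **mobility**: solve the dense coupled system so the fluid velocity
  matches the prescribed velocity at every node exactly.  The solve
  reproduces node velocities to better than 1e-6 relative (tested).

The choice is not cosmetic.  Under any *per-rod* force law — resistive
included — the cycle-average of each rod's force field is invariant to
a shift of that rod's phase, so the time-averaged Eulerian flow of a
cilia array is *mathematically independent of metachronal phase lags*;
only weak Lagrangian (Stokes-drift) effects remain.  Phase coordination
changes the mean flow only through hydrodynamic interaction between
cilia, which the mobility solve captures: when neighbours beat in
phase they screen one another (sharing the load of dragging the same
fluid), and the forces the solve returns depend on the whole
instantaneous configuration.  Cluster and array scenarios therefore
default to mobility mode.  Its cost is kept modest by exploiting
periodicity: every integrator stage falls on one of
`3 * steps_per_cycle` beat phases, so the dense solves are performed
once per distinct phase and reused for all cycles.  Tissue-patch
scenarios (hundreds to thousands of nodes) default to resistive
forcing, which preserves swirl geometry at a fraction of the cost; the
full-scale study script can switch them to mobility.

The simulation is nondimensionalized with lengths in micrometres,
`mu = 1`, and time kept in seconds (or beat cycles; 18 Hz converts).
Absolute force and pressure scales are not observable in tracer
geometry, which is why the package reports transport in micrometres per
beat cycle rather than in force units.

## Geometries

* `build_cluster()`: one 3x3 cluster, rod spacing `D = 4` um, so the
  cilia span an 8 um x 8 um footprint.
* `build_array()`: three clusters in a line along x (the airway axis),
  centre-to-centre spacing `Dc` from `3D` to `12D`.  At `Dc = 3D` the
  effective 12 um footprints touch and the 27 rods form one continuous
  uniform lattice; that is the sense in which `3D` means "adjacent",
  and it is why the centre-to-centre convention with a `3D` effective
  footprint is the default (the 8 um nominal footprint is retained for
  density bookkeeping, where it represents the area the cilia occupy).
* `sample_patch()`: a `100 x 100` um tissue patch with cluster centres
  drawn uniformly at random under a 12 um minimum-separation
  (no-overlap) constraint, targeting `round(density * area / 64)`
  clusters.  Placements are reproducible from an integer seed, and the
  ensemble distribution of centres is uniform over the admissible
  region (chi-squared tested).
* `assign_phases()`: metachrony is imposed, not emergent.  Within each
  cluster the three columns (by x) get offsets `0, phi0, 2*phi0`;
  positive `phi0` is the antiplectic convention of the mucociliary
  literature, negative symplectic.  At `phi0 = 2*pi/3` the lag
  accumulated over the three columns is a full `2*pi`.

## Tracers and observables

Tracers are seeded on regular lattices in configured boxes, with the
labelling conventions used by the analyses: four colour groups by
initial x-quartile, bottom/top halves by initial z, or z-bands.
Default study regions: `[-50, 50]^2 x [5, 9]` um (tissue patch and
cluster arrays, near the cilia tips), `[-20, 20]^2 x [1, 9]` um
(single cluster).

* `center_of_mass()` - the unweighted mean tracer position per
  snapshot; its x-component is the scalar clearance measure.  Times
  are labelled in beat cycles and in both second conversions (18 Hz
  and 36 Hz) because the figure conventions in this literature mix the
  two; the cycle count is canonical here.
* `mixing_number()` - Eq.-style nearest-neighbour statistic: the
  geometric mean over group-1 tracers of the squared distance to the
  nearest group-2 tracer, computed in log space, exactly zero only for
  coincident points.  It is asymmetric in the group order; the package
  computes it as written (group order logged in the output) with an
  optional symmetrized variant.  Positions enter as full 3-vectors.
* `ripley_k()` - the unadjusted estimator
  `K(r) = A/(n(n-1)) * #{pairs with d <= r}` on 2-D projections within
  a window, against the CSR reference `pi r^2`.  The crossing radius
  `r0` (first positive-to-negative crossing after the initial
  exceedance, linearly interpolated) measures the swirl-trapping
  scale.  No edge correction by default - the analysis windows are
  large compared with `r0` - with a translation correction available.
  The tip layer "at z = 7 um" is the band `|z - 7| <= 1` um.
* `cycle_averaged_field()` - the mean flow over 64 equispaced phases
  of one beat on a grid at fixed height (default `z = 7` um, 2 um
  spacing), with planar vorticity by central differences.

## Numerical choices

* RK4 with phase advanced at substage times; `steps_per_cycle = 100`
  by default (even values keep the stroke switches on step
  boundaries).  The length law's one-sided derivative at the stroke
  switches would cost the integrator its order if a stage sampled the
  wrong branch exactly at the switch, so the first and last stage
  times of each step are nudged into the step interior by a relative
  1e-9.  Self-convergence is fourth order (slope >= 3.5 tested); over
  hundreds of cycles individual trajectories are chaotic, so
  statistics (centre of mass, mixing number, K function), not
  pointwise positions, are the reproducible observables.
* Tracer counts default to 2000 (patch), 1000 (arrays), 500 (single
  cluster); all analyses are count-robust (means, geometric means, K
  normalization).  The test suite runs reduced problem sizes -
  typically 150-500 tracers, 20-24 steps per cycle and 50-150 cycles -
  chosen so every qualitative contract is resolved; the long-run
  script in `inst/scripts/` runs the full-fidelity sizes (2000
  tracers, 100 steps per cycle, 400 cycles).
* The resistive `gamma` calibration is a single scalar per
  configuration; it is computed analytically from one kernel
  evaluation and logged in the `cilia_system` print method.
* Patch placement uses rejection sampling capped at 1e5 draws; an
  unplaceable density warns and reports the achieved count.
  Cluster-count rounding is round-to-nearest.

## What the simulations show

With the defaults the package reproduces the qualitative physics that
motivates the model:

* a single synchronized cluster generates one counter-clockwise swirl
  whose tracers drift towards negative x and y while slowly rising;
* three clusters interact hydrodynamically, and net transport depends
  non-trivially on their spacing;
* imposed metachronal phase lags reorganize the flow through
  hydrodynamic screening: small antiplectic lags weaken x-clearance
  substantially (by more than half at `phi0 = pi/12`), and the
  `pi/3` antiplectic wave accelerates vertical mixing relative to
  synchrony over the first hundred cycles;
* random tissue patches develop mesoscale swirls whose Ripley-K
  crossing radius grows with ciliary density.

These are statements about this idealized model: a Newtonian fluid (no
mucus viscoelasticity or periciliary layering), prescribed rigid-rod
kinematics (no elastohydrodynamics, no emergent synchronization), and
massless tracers (no diffusion or finite-size effects).  Passing tests
demonstrate internal correctness and these qualitative behaviours at
reduced scale, not quantitative agreement with airway physiology.

## Known limitations

* Quantitative velocity magnitudes depend on the forcing scale, which
  the resistive calibration fixes by convention; only flow geometry,
  rankings and trends are meaningful across configurations.
* The polar-angle law is a declared modelling choice (see above); the
  transport direction is robust to it only insofar as the law breaks
  the stroke height symmetry.
* The wall image system enforces the no-slip condition exactly for
  blob forcing, but reciprocity of the node-to-node coupling matrix
  holds only to O(eps^2/h^2) because the blob is smoothed on one side;
  at the default `eps` this is a 1e-6 relative effect.
* Long-horizon individual trajectories are chaotic; all conclusions
  should be drawn from ensemble statistics.

## A worked example

```{r example, eval = FALSE}
library(ciliaflow)

cfg <- scenario_config("single_cluster",
                       tracers = list(n = 500),
                       integrator = list(steps_per_cycle = 30L,
                                         duration_cycles = 50L))
run <- run_scenario(cfg)
com <- center_of_mass(run$trajectories[[1]])
tail(com, 1)             # negative xc, positive zc drift
plot(run$trajectories[[1]])
```
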