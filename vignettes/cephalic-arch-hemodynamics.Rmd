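---
title: "Modelling cephalic-arch hemodynamics from venogram and IVUS imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cephalic-arch hemodynamics from venogram and IVUS imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(archflow)
```

## The problem

Most hemodialysis patients with an arteriovenous fistula receive a
brachiocephalic configuration, in which arterialized flow drains through the
cephalic vein and its terminal bend — the cephalic arch — into the axillary
vein. The arch is the most common site of outflow stenosis. The hemodynamic
quantities thought to drive that remodelling (wall shear stress, pressure,
recirculation) cannot be measured directly in vivo, but they can be computed
by simulating blood flow through a patient-specific reconstruction of the
arch lumen.

`archflow` implements that pipeline end to end:

1. **Venogram processing** — a 2D contrast projection of the arch is reduced
   to a vessel centerline and an arch angle (minimum-intensity projection,
   Otsu binarization, component cleaning, Zhang–Suen skeletonization,
   longest-geodesic path ordering).
2. **IVUS processing** — catheter-pullback cross-sections give per-slice
   lumen contours, areas, and equivalent diameters
   (`d = 2 * sqrt(A / pi)`); the abrupt diameter shift where the catheter
   leaves the axillary vein aligns the pullback with the centerline.
3. **Geometry** — contours are placed on planes perpendicular to the
   centerline at 1 mm stations using parallel-transport frames, lofted into
   a watertight triangulated surface, and demarcated into pre-bend, bend and
   post-bend regions. Constrictions are flagged as regions of interest.
4. **Flow simulation** — steady and pulsatile incompressible laminar
   Navier–Stokes flow through the lumen, with a fully developed inlet at the
   Doppler-measured velocity, a fixed outlet pressure, no-slip rigid walls,
   Newtonian rheology at the measured whole-blood viscosity.
5. **Derived metrics** — Reynolds numbers (`Re = rho u L / eta`), per-region
   maxima, normalized velocity profiles, wall shear stress
   (`tau = eta * shear rate`), cell Reynolds numbers
   (`Re_cell = rho |u| h / eta`), low-WSS patches, recirculation flags, and
   cohort summary statistics.

Because no imaging data are deposited with the study this package follows,
a first-class synthetic-data module generates venogram-like projections,
IVUS-like contour stacks, and patient parameter records with known ground
truth; every downstream stage is tested against that truth.

## Units and conventions

* Geometry (centerlines, meshes, contours) is in **millimetres**; STL/VTK
  exports are therefore millimetre-valued (STL itself is unitless).
* Clinical quantities keep their reporting units: areas in cm², diameters in
  cm, velocities in cm/s in tables (m/s inside the solver), viscosity in cP
  in tables (Pa·s inside the solver), pressures in mmHg at the interface
  (1 mmHg = 133.322 Pa).
* The arch angle is the inscribed angle between tangents fitted to the two
  straight arms, in (0, 180]: 180 is a straight vessel and smaller values
  are more acute bends (measured arches remodel from ~137 to ~125 degrees).
* Reported Reynolds numbers are rounded half-away-from-zero to integers,
  the convention of the clinical tables; `rounded = FALSE` gives the raw
  value.
* Mean lumen diameter is computed from the **mean area**, not as the mean of
  per-slice diameters, and spreads are sample standard deviations (n − 1).

## The solver

The momentum and continuity equations

```
rho (u . grad) u = div[ -p I + eta (grad u + grad u^T) ] + F,   div u = 0
```

are discretized on a uniform marker-and-cell (MAC) staggered grid voxelized
from the lumen (pressure at cell centers, velocity components on faces) and
advanced by a fractional-step projection scheme: explicit first-order upwind
advection, explicit viscous update, and an exact discrete pressure
projection by sparse Cholesky factorization, which enforces the divergence
constraint to solver precision every step — inlet and outlet fluxes agree to
round-off at convergence. Steady solutions are obtained by pseudo-time
marching from a parabolic initial guess until the normalized momentum
residual `max|du| d / (dt u_ref^2)` falls below the steady relative
tolerance (default 0.001); transient runs sub-step at the advective CFL
limit and emit snapshots every 0.05 s over 1.5 s (longer than one pulse
cycle at every measured pulse rate), starting from the steady solution at
the waveform's initial velocity. The per-snapshot continuity residual must
stay below the transient tolerance (default 0.01).

Two numerical choices matter for accuracy:

* **Sub-cell wall distances.** The no-slip condition is imposed at the true
  lumen surface, not the staircase voxel boundary: near-wall viscous
  stencils use Shortley–Weller one-sided differences with the fractional
  wall distance from the tube signed-distance function, floored at
  `theta_min = 0.25` for explicit stability. At the default resolution of
  16 cells across the diameter this reproduces the Hagen–Poiseuille
  pressure drop to ~1% and halving the cell size changes it by well under
  2%; with a floor of 0.5 the bias grows to ~8%, which is why 0.25 is the
  default.
* **Wall shear sampling.** WSS is estimated from cells between 0.5 and 1.5
  cells from the wall — the first fully interior ring, where discrete
  velocities are accurate — extrapolated to the wall over the true distance
  with the quadratic correction `1/(1 - d/2r)` that is exact for Poiseuille
  flow (measured accuracy ~1–2% in the tube benchmark; first-ring sampling
  without the interior offset is 15–20% biased).

The rigid-wall, Newtonian assumptions mirror the physiological argument
that whole blood at these shear rates behaves effectively Newtonian and
that wall compliance is secondary for the quantities of interest; the body
force `F` defaults to zero (gravity neglected). Doppler peak systolic
velocity is applied as the **cross-section mean** of the fully developed
inlet profile, matching the average-velocity semantics of fully-developed
inlet boundary conditions in standard FEM practice; centerline velocities
are therefore up to twice the nominal value. Outlet pressure defaults to
23 mmHg for steady runs, with 20 mmHg (3-month) / 23 mmHg (12-month)
conventional for pulsatile runs; the measured averages 19.88/23.3 mmHg can
be passed explicitly.

### Inlet waveforms

The pulsatile inlet follows `(u_max - u_min) sin(2 pi f t) + u_min` at the
measured pulse frequency. Taken literally this dips to `2 u_min - u_max`
in the second half-cycle, below the measured diastolic velocity (and below
zero whenever `u_max > 2 u_min`); whether the original analysis clipped or
offset the trough is not stated. Both variants are exposed
(`variant = "literal"` and `"clipped"`); peak-phase behaviour, which all
quantitative checks use, is identical. Square waves hold `u_max` for the
duty fraction of each period; the sawtooth rises over 80% of the period and
falls over 20%, so the diastolic-to-systolic transition is the slow one.

### Asymmetry of bend profiles

Flow in a curved pipe is not axisymmetric. Two distinct effects contribute:

* a geometric tilt of order `a / R_bend` (lumen radius over bend radius)
  that exists **even in creeping flow** — fluid near the inner wall travels
  a shorter path, so the profile tilts inward; for this package's default
  arch (`a/R = 0.24`) the mirror asymmetry from this effect alone is
  0.10–0.15 at any Reynolds number, and
* the inertial (Dean) skewing toward the outer wall, which grows with
  Reynolds number and is the physiologically interesting signal.

The asymmetry index is therefore defined as `|u_inner - u_outer| / u_max`
with `u_inner`, `u_outer` the **peak** speeds over the inner and outer
half-diameters: a pure tilt moves the peak without changing its height and
contributes only at second order, while Dean flattening changes the
half-peak difference at first order. The index is evaluated one diameter
downstream of the bend exit — where the creeping-flow tilt has relaxed (its
redevelopment length at low Reynolds number is about one diameter) but the
high-Reynolds Dean skew persists — which is also where the post-bend
asymmetry reversal is clinically described. At 70 cm/s in the idealized
0.95 cm / 125-degree arch the index is ~0.1; at 1 cm/s it is below 0.01.

### Patient stand-in geometries

Patient lumen reconstructions are not published, so pulsatile and
reduced-velocity experiments run on idealized stand-ins parameterized by
the patient's measured values: for the high-flow patient (P96, 3-month
record) a 0.66 cm arch bent at 133 degrees with a focal 40% stenosis at the
bend (cosine-tapered over 0.5 cm — a ~14-degree expansion; a taper spread
over 1 cm is a gentle ~8-degree diffuser that does not separate and does
not represent a focal lesion). With the measured sinusoidal inlet
(38.3–66.6 cm/s at 101 beats/min, Re 1574 at peak) a recirculating cluster
forms downstream of the throat near peak systole and disappears when the
inlet velocity is reduced to 10% (Re 157), at both grid resolutions checked
(11 and 14 cells across the diameter).

## The synthetic-data generator

`arch_spec()` describes a vessel as two straight arms joined by a circular
bend with optional focal stenoses (cosine-tapered area reduction — smooth
tapers avoid meshing and solver artifacts of step changes).

* `render_venogram()` draws the tube's planar projection with
  darker-than-background contrast and per-frame Gaussian noise; the
  centerline is planar because a venogram is a single projection — the same
  limitation the clinical pipeline has, recorded here deliberately: the
  reconstructed centerline is lifted to z = 0 and all out-of-plane shape
  comes from the IVUS contours.
* `render_ivus_stack()` emits one lumen cross-section per 1/30 mm of
  pullback (the 30 fps / 1 mm/s convention; frames are 500 × 500 px over
  16 × 16 mm by default, i.e. 0.032 mm/px), with a 1 cm axillary lead-in at
  1.5× diameter so arch-start alignment has the abrupt diameter shift it
  needs, and per-vertex radial tracing noise. Ground-truth contours are
  produced for every frame; mask images are rasterized at a configurable
  stride (default: the every-30th-frame subset the pipeline consumes),
  since rasterizing every frame of a long pullback would occupy gigabytes.
* `gen_patient_records()` draws records spanning the measured clinical
  ranges (systolic velocity 9.4–66.6 cm/s, WBV 2.68–4.63 cP, pulse 71–101
  beats/min, diameter 0.66–1.1 cm). Independent uniform marginals can
  combine into Reynolds numbers (~2900) that no measured patient reaches,
  so records are rejection-resampled until `Re` lies in [100, 2100] — the
  generator models the joint constraint, not just the marginals.

What the generator does **not** emulate: IVUS speckle texture and flow
color, catheter/wire artifacts, collateral vessels in venograms, breathing
or cardiac motion, non-circular (elliptical or crescentic) lumen shapes.
Passing round-trip tests therefore demonstrate the correctness of the
geometric and numerical machinery on clean, tube-like data, not robustness
to real clinical image quality; real grayscale IVUS segmentation is out of
scope by design (the package consumes traced masks or contours).

## Worked example

```{r example, eval = FALSE}
# cohort arithmetic
cohort <- cephalic_cohort()
summ <- cohort_summary(cohort)
summ$by_timepoint[, c("timepoint", "mean_diameter_cm", "mean_re")]

# idealized arch, steady flow at 70 cm/s
arch <- make_idealized_arch()          # 0.95 cm, 125 degrees
domain <- discretize(arch, cells_across_diameter = 12)
props <- fluid_properties(density = 1060, viscosity = 3.45e-3)
cond <- flow_conditions(inlet_waveform("constant", u_max = 0.70))
field <- solve_steady(domain, props, cond, on_nonconvergence = "warn")
region_maxima(field)
detect_low_wss(compute_wss(field), domain)
```

## Numerical choices and degenerate inputs

* Threshold default is Otsu on the projected venogram (the standard default
  of general-purpose binarization); a numeric threshold can be passed.
* Skeleton ordering takes the longest weighted geodesic between endpoints,
  which prunes side branches (collateral spurs); a closed-loop skeleton
  with no endpoints is an error. How the original analysis excluded
  branches is unstated; longest-path pruning is this package's choice.
* The arch-start heuristic (`find_arch_start`) uses a 25% relative median
  diameter shift over 5 mm windows after a 3-slice median filter; the
  clinical description ("rapid shift in diameters") gives no number, so
  this operationalization is a documented choice. A constant-diameter
  pullback returns index 1 with a warning.
* Contour placement uses parallel-transport frames, never Frenet frames
  (Frenet normals flip at inflections and would corrupt the loft), and
  rings are rotationally registered to the previous ring by the
  minimal-distance cyclic offset.
* Laplacian smoothing of the loft is limited (default 10 iterations) and
  followed by a volume-preserving rescale.
* Region demarcation accumulates **signed** in-plane turning (pixel-level
  tangent noise cancels in the signed sum); the bend is the smallest
  window containing 80% of total turning. A straight vessel yields all
  pre-bend with a warning.
* "Randomly chosen" per-region slices default to the deterministic region
  midpoint; literal random choice is available behind an explicit seed.
* Degenerate inputs error loudly and name the offending field: empty
  masks, single-pixel components, self-intersecting polygons, stacks
  longer than their centerline, non-watertight surfaces, geometries
  thinner than 4 cells, negative evaluated waveforms.

## Problem sizes

The shipped tests and the acceptance script run the tube benchmark at the
default 16 cells across the diameter (~50,000 fluid cells), the idealized
arch at 12, and the pulsatile stand-in at 11 and 14; arm lengths of 1.5–3 cm
keep domains compact while leaving several diameters of straight vessel on
each side of the bend. These sizes were chosen as the coarsest grids that
pass the analytic gates (Poiseuille profile, Hagen–Poiseuille pressure
drop, wall shear, flux balance) with margin; all of them run on a single
CPU core.

## Known limitations

* The centerline from a single venogram projection is planar; real arches
  are not. Out-of-plane geometry enters only through the IVUS contours.
* Cross-sections are modelled as star-shaped about their centroid in the
  synthetic generator, and the solver voxelizes the lumen from the
  centerline and the per-station equivalent radius — strongly non-circular
  lumens are represented by their equivalent-area tube.
* First-order upwind advection adds numerical diffusion; separation and
  recirculation onset thresholds are resolution-dependent (hence the
  two-resolution stability check).
* At global Reynolds numbers approaching 2000 a genuinely steady solution
  may not exist; the steady solver then reports its residual history and
  can return the quasi-steady state with a warning instead of erroring.
* No fluid–structure interaction, no turbulence model, no non-Newtonian
  rheology, no branch/bifurcation meshing, and no registration of repeat
  studies beyond arclength-fraction matching of regions of interest.
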