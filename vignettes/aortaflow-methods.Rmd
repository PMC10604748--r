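---
title: "Quantifying thoracic-aorta hemodynamics from 4D flow MRI: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying thoracic-aorta hemodynamics from 4D flow MRI: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope

`aortaflow` turns two inputs — a time-resolved three-directional
phase-contrast MRI velocity field (4D flow MRI) and an integer-labelled
segmentation of the cardiovascular structures — into the standard
hemodynamic readouts used to compare tricuspid (TAV) and bicuspid (BAV)
aortic-valve subjects: flow-rate curves and cardiac metrics, transit-time
pulse wave velocity (PWV) with Bramwell-Hill distensibility, short-axis
axial vorticity, chord profiles of velocity, and axial/tangential wall
shear stress (WSS) with the oscillatory shear index (OSI). Segmentation
itself is out of scope: masks are inputs (from any segmenter, neural or
manual), and the package evaluates them (Dice score, cross-sectional
areas) rather than producing them.

Because clinical 4D-PCMRI datasets are rarely redistributable, the package
ships a synthetic aorta flow phantom that emulates the statistical and
kinematic structure these analyses assume. Every downstream stage is
exercised against the phantom's programmed ground truth.

## Data model and units

Velocity fields are 5-D arrays `[x, y, z, frame, component]` in cm/s (the
native phase-contrast convention); masks are 3-D integer lattices sharing
the spatial grid. World coordinates are axis-aligned,
`world = origin + (index - 1) * spacing` in mm; oblique acquisitions are
rejected at the I/O layer rather than silently resampled. All physics
converts to SI internally; outputs use the units the clinical literature
prints (mL/s, L/min, m/s, 1/mmHg, mmHg, Pa, 1/s).

Two constants the measurement itself cannot supply are configurable with
standard whole-blood defaults: density 1060 kg/m^3 (enters kinetic
energy and Bramwell-Hill) and dynamic viscosity 3.5 mPa s (scales every
shear stress linearly — reported WSS values are proportional to the
chosen viscosity).

## Flow quantification

Flux through an analysis plane is the sum of the through-plane velocity
component times the effective per-voxel cross-section area, over the
labelled voxels whose centres lie within half a slab thickness of the
plane. This nearest-voxel gather is the default because it is robust on
coarse, anisotropic grids (2.4 mm slices against 0.9 mm in-plane); a
trilinear variant is available as an option flag. Planes carry an
in-plane sampling radius so a plane through a curved vessel samples only
the local cross-section and not the opposite limb of the arch.

Volumes are periodic trapezoidal integrals over one cycle (on a uniform
frame grid this equals the Riemann sum), the regurgitant fraction is
`100 * backward / forward`, and cardiac output is
`net volume x heart rate / 1000`. Kinetic energy is
`0.5 rho sum(|v|^2) dV` over the labelled blood pool, in mJ.

## Arterial stiffness

PWV uses the transit-time method: the distance between the ascending and
descending analysis planes divided by the delay between the feet of their
flow curves. The foot is the intersection of the upslope tangent with the
pre-systolic baseline (mean of the lowest quartile of samples). At 30
phases per cycle a tangent taken at a single maximum-slope sample is
dominated by sampling-phase quantisation — its position jitters by
several milliseconds depending on where the frames happen to fall on the
upslope, which is the same order as the transit time itself (~20-30 ms).
The package therefore fits the tangent by least squares to the mid-upslope
of the periodic-spline-upsampled curve (samples between 25 % and 90 % of
the baseline-to-peak amplitude, the peak refined by a local parabola);
on a linear upslope this reduces exactly to the classical tangent. On
frame-sampled curves this construction locates relative foot shifts to
well under a millisecond, which is what a 5 % PWV error budget requires.

Distensibility is the Bramwell-Hill relation `D = 1 / (rho PWV^2)`,
reported per mmHg. The area pulsation dA/A compares the lumen area at
peak systole (maximum flux) with end diastole (last frame before the
foot), with the end-diastolic area as denominator; the pressure drop is
`(dA/A) / D`. With rho = 1060 kg/m^3 these relations reproduce each
other's published clinical values to the printed precision, which is the
package's internal consistency check.

## Short-axis fields, chords, WSS and OSI

`extract_plane()` interpolates the velocity trilinearly onto a square
in-plane lattice (default resolution: the finest voxel spacing) and
decomposes it into through-plane and in-plane components; the lumen
indicator is the nearest-voxel mask label. Axial vorticity is
`dv/dx - du/dy` by central differences, one-sided at the lumen boundary;
positive values are counter-clockwise about the flow direction.

Chord profiles run wall-to-wall through the lumen centroid along the
convex-concave diameter, with x/X = 0 at the convex (outer-curvature)
wall. The wall position is estimated from the outermost lattice cell
whose centre is labelled lumen — cell centres are known exactly, whereas
the boolean indicator boundary overshoots the wall by up to half a cell.
Shear stress is the chord-directional derivative of each velocity
component (`tau_ax = mu dw/ds`, `tau_tan = mu du_c/ds`), central in the
interior and second-order one-sided at the walls; this is the profile
quantity the clinical figures plot, not the full wall-traction tensor.
OSI is `0.5 (1 - |mean shear| / mean |shear|)` over the cycle, 0 for
unidirectional and 0.5 for fully oscillatory shear, defined as 0 when the
shear vanishes identically.

For the summary wall values, `wall_shear_summary()` makes two
robustness choices appropriate to voxelised data: the chord endpoints are
inset by one lattice cell (interpolation within a cell of the wall mixes
in exterior voxels and flattens the profile foot), the wall
gradient is a least-squares slope over a two-cell near-wall window rather
than a single one-sided difference, and peak-systolic values average the
peak frame with its two neighbours on each side. On noise-free analytic
profiles (Poiseuille) the plain chord estimator recovers the closed-form
wall shear to better than 2 %, so these settings are defaults of the
summary, not of the underlying operators.

## The synthetic phantom

The phantom is a kinematic construction, not a fluid-dynamics solution;
it contains exactly the structure the estimators consume:

* **Geometry.** A planar candy-cane centreline: straight ascending limb
  (20 % of the aortic length), 180-degree arch (45 %), straight
  descending limb (35 %), with a circular lumen. Torsion and branch
  vessels (head and neck arteries) are omitted — the exercised analyses
  do not require them, and the segmentations being emulated did not
  include them. An ellipsoidal left-ventricle blob provides the
  evaluation-plane logic with a second structure; it is not scaled to
  anatomical LV volume.
* **Waveform.** One half-sine systolic lobe lasting a third of the cycle
  plus a small negative early-diastolic lobe (a tenth of the cycle). The
  sampled lobes are rescaled on the frame grid so the discrete forward
  and net volumes are exact; voxel velocities evaluate the continuous
  waveform so that plane curves are clean samples of the delayed
  waveform rather than resampled interpolants.
* **Transit delay.** The waveform phase at each voxel is delayed by
  arclength / PWV — the minimal structure the transit-time estimator
  needs, rather than a wave-propagation simulation.
* **Jet profile.** A top-hat with a linear near-wall ramp of thickness
  0.3 lumen radii. In BAV mode the profile is linearly skewed toward the
  convex wall, placing the peak at x/X = 0.15 (the skew integrates to
  one over the disc, so programmed fluxes are unaffected).
* **Secondary flow.** TAV: a mirrored Dean-like vortex pair from a
  stream function odd in the binormal coordinate — zero net circulation,
  velocity vanishing at the wall. BAV: a Lamb-Oseen vortex (core radius
  0.2 lumen radii) centred at x/X = 0.7 toward the concave wall — axial
  vorticity positive everywhere, so the plane-mean vorticity signature
  of counter-clockwise helical flow is unambiguous, and the 1/r velocity
  tail produces the elevated tangential WSS at the concave wall. Peak
  in-plane speed is `swirl_ratio` (default 0.4, a free modelling choice:
  no quantitative vortex strength is published) times the local peak
  axial speed.
* **Wall pulsation.** The lumen radius scales by `sqrt(A(t)/A0)` with
  `A(t)/A0 = 1 + (dA/A) * normalized flux`, so the programmed area
  pulsation appears between end diastole and peak systole.
* **Noise and venc.** Additive Gaussian noise per component, independent
  across voxels and frames (default 5 cm/s, 2.5 % of the 2 m/s venc),
  then per-component clipping at the venc with a clipped-voxel count
  recorded. Velocity-to-noise-ratio modelling and phase-wrap aliasing
  are not emulated.
* **Flux calibration.** The axial amplitude divides by the *discrete*
  effective profile area measured on a reference cross-section of the
  actual voxel grid, so the programmed waveform is reproduced exactly on
  the grid rather than up to a voxelisation bias. The phantom's internal
  area sum and the analysis-side `plane_flux()` remain independent
  computations.

Default conditions are per-valve-mode physiological values (TAV: 70 bpm,
67 mL, 0.3 % regurgitation, 112 mm aortic length, PWV 3.9 m/s, dA/A
0.30; BAV: 47 bpm, 108 mL, 1.5 %, 156 mm, 3.8 m/s, 0.27; lumen radii 10
and 11 mm giving ascending areas in the published 2-4 cm^2 range). The
default generation grid keeps the acquisition voxel spacing
(0.9 x 0.9 x 2.4 mm) and 30 frames but trims the field of view to
96 x 96 x 60 voxels; the full 320 x 320 x 100 acquisition matrix is
available via `phantom_grid("full")` but a double-precision dataset at
that size is ~7 GB, which no documented workflow needs.

### What passing phantom tests does and does not show

The phantom shares with real data the features the estimators rely on:
frame-quantised sampling of a delayed waveform, voxelised masks with
partial-volume walls, venc-scaled additive noise, and mode-specific
secondary-flow topology. It does not contain turbulence, valve-leaflet
jets, wall motion other than radial pulsation, branch outflow (so
ascending and descending net flows are equal by construction, unlike in
vivo where the head-and-neck vessels divert flow), eddy-current offsets,
or phase wraps. Parameter-recovery results therefore validate the
estimator implementations and their discretisation behaviour — not the
estimators' robustness to acquisition artefacts.

## Numerical tolerances and degenerate inputs

* Phantom recovery at the reduced grid (tested over three noise seeds in
  both modes): stroke volume within 2 %, regurgitant fraction within
  0.3 percentage points, PWV within 5 %, dA/A within 0.03.
* Dice of two empty sets is 1 (absent and predicted absent agree);
  group statistics use the sample (n - 1) standard deviation, which is
  what reproduces published per-case aggregates.
* A label missing from a requested slice yields area 0 with a warning;
  a plane that misses the lumen, a flow curve without a positive
  upslope, zero forward volume, and a chord thinner than two lattice
  cells are errors, not silent zeros.
* Ties in peak-frame selection resolve to the earliest frame; the
  lowest-quartile baseline makes the foot robust to the small negative
  regurgitant lobe.

## Problem sizes

The test suite and the acceptance script generate phantoms at the
reduced 96 x 96 x 60 grid with 30 frames (about half a million voxels,
~50 million velocity samples per dataset); a generation plus a full
analysis pass takes on the order of ten seconds each. Unit tests of the
field operators use analytic lattices of a few hundred cells squared.
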