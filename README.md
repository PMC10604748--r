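# aortaflow

Hemodynamic analysis of the thoracic aorta from 4D phase-contrast MRI
(4D flow MRI).

Subjects with a bicuspid aortic valve (BAV) develop characteristically
different blood-flow patterns in the ascending aorta than subjects with a
normal tricuspid valve (TAV): an eccentric valve jet, helical
counter-clockwise secondary flow, and asymmetric wall shear stress — all of
which bear on valve incompetence and aortic dilation risk. Quantifying them
from a 4D-PCMRI acquisition requires a chain of standard computations that
this package implements as a tested, reusable pipeline for imaging
scientists and cardiovascular-biomechanics researchers:

* **Flow quantification** through analysis planes: flux curves, net /
  forward / backward volumes, regurgitant fraction, cardiac output
  (`CO = V_net × HR / 1000`), plane-mean velocity and kinetic energy
  (`KE = ½ρ Σ|v|² ΔV`).
* **Arterial stiffness**: transit-time pulse wave velocity from the feet of
  the ascending and descending flow curves (`PWV = ΔL / Δt`, tangent
  time-to-foot method), Bramwell–Hill distensibility `D = 1/(ρ·PWV²)`,
  systolic area pulsation ΔA/A, and pressure drop `ΔP = (ΔA/A)/D`.
* **Short-axis hemodynamic fields**: trilinear plane extraction, axial
  vorticity `ω = ∂v/∂x − ∂u/∂y`, wall-to-wall chord profiles, axial and
  tangential wall shear stress (`τ = μ ∂v/∂s`) and the oscillatory shear
  index `OSI = ½(1 − |∫τ dt| / ∫|τ| dt)`.
* **Segmentation evaluation**: Dice score `2|A∩B|/(|A|+|B|)`,
  cross-sectional areas on the mid-LV axial plane, group mean ± sample SD.
* **A synthetic TAV/BAV aorta flow phantom** — curved-tube geometry,
  systolic waveform with transit delay, top-hat valve jet (symmetric with a
  Dean vortex pair in TAV mode; skewed with a single counter-clockwise
  vortex in BAV mode), wall-area pulsation and venc-scaled noise — so the
  entire pipeline is testable against programmed ground truth without
  patient data.

Velocity fields and label masks are exchanged as NIfTI volumes with a YAML
sidecar for acquisition metadata (venc, frame interval, label vocabulary).
Analysis results are tibbles that compose with the tidyverse; fitted results
have `tidy()`/`glance()` methods and `autoplot()`/`plot_plane()` helpers.

## Worked example

Generate a BAV phantom and run the full analysis:

```r
library(aortaflow)

ph    <- generate_phantom(phantom_config("BAV", seed = 7))
asc   <- plane_at(ph$geometry, 0.15)   # ascending aorta plane
desc  <- plane_at(ph$geometry, 0.85)   # descending aorta plane
curve <- compute_flow_curve(ph$velocity, ph$masks, "aorta", asc)

flow_metrics(curve, heart_rate_bpm = 47)
#> # A tibble: 1 × 7
#>   heart_rate_bpm net_volume_ml forward_volume_ml backward_volume_ml
#> 1             47          108.              110.               1.64
#>   regurgitant_fraction_pct peak_flux_ml_s cardiac_output_l_min
#> 1                     1.49           400.                 5.08
```

The net volume (108 mL), regurgitant fraction (1.5 %) and cardiac output
(5.1 L/min) recover the phantom's programmed physiology. Stiffness from the
two flow curves and the per-frame lumen areas:

```r
fit <- assess_stiffness(curve,
                        compute_flow_curve(ph$velocity, ph$masks, "aorta", desc),
                        area_curve(ph$masks, "aorta", asc),
                        0.7 * ph$config$aortic_length)
fit
#> <stiffness_fit> PWV 3.85 m/s (L 109 mm, transit 28.4 ms), D 0.0085 /mmHg,
#>                 dA/A 0.277, dP 32.6 mmHg
```

The recovered PWV (3.85 m/s, programmed 3.8) and ΔA/A (0.277, programmed
0.27) are within the estimator tolerances. Wall shear stress at the chord
endpoints on the ascending plane:

```r
wall_shear_summary(ph$velocity, ph$masks, "aorta", asc)
#> # A tibble: 2 × 6
#>   side    x_norm tau_ax_peak_pa tau_tan_peak_pa osi_ax osi_tan
#> 1 convex       0          1.21          -0.0732 0.0875   0.468
#> 2 concave      1          0.707          0.101  0.104    0.207
```

The BAV signature is visible: elevated axial wall shear at the convex wall
(x/X = 0, toward the fused-leaflet raphe) and non-zero tangential shear at
the concave wall (x/X = 1) from the counter-clockwise helical flow — a TAV
phantom shows symmetric axial shear and near-zero tangential shear.
`autoplot(curve)`, `autoplot(shear_profile(chord_profile(...)))` and
`plot_plane(..., "vorticity")` draw the corresponding figures. The methods
vignette (`vignettes/aortaflow-methods.Rmd`) documents the models,
estimator design and phantom assumptions.

A thin command-line wrapper is included:

```sh
Rscript inst/scripts/aortaflow.R all --mode bav --seed 7 --out results/
```

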