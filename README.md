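# aqueduct

Non-invasive quantification of the pressure difference across the cerebral
aqueduct from MRI.

The aqueduct of Sylvius — the narrow channel between the 3rd and 4th
ventricles — is the dominant resistive segment of the ventricular CSF
pathway, so the pressure difference ΔP across it approximates the
transmantle pressure (ventricles vs subarachnoid space), a quantity of
interest in hydrocephalus and CSF-circulation physiology that is otherwise
only measurable with invasive sensors. `aqueduct` implements the full
post-processing chain that turns two routine acquisitions into ΔP:

1. **Morphology → hydraulic resistance.** A high-resolution steady-state
   volume (e.g. balanced FFE, 0.6 × 0.6 × 1.2 mm³) is projected
   (maximum-intensity projection over 2–3 sagittal slices), resampled to
   0.03 mm, binarized at a threshold taken from the steepest intensity
   transition along an operator-drawn line, and reduced to a centerline
   with per-element perpendicular-chord diameters. Each of the (default
   100) equal-arc-length elements contributes a Poiseuille resistance

   R_i = 128 µ ΔL_i / (π D_i⁴),   µ = 0.71 mPa·s,

   in mPa·s/mm³; the distal endpoint is standardised at 95% of the total
   cumulative resistance. Summary morphometrics (L, Ls, L/Ls, D-mean,
   D-min, mean Womersley number, peak Reynolds number) come with it.

2. **Real-time phase contrast → flow decomposition.** An ungated 2D+t
   velocity series (2 × 2 mm², 87 ms/frame, venc 10 cm/s) is processed by
   cardiac-frequency ROI detection, temporal de-aliasing, stationary-tissue
   background correction, per-cycle segmentation at the flow minima, and
   cubic-spline resampling of every cycle to 32 phase points. The ensemble
   mean curve and its 95% limits of agreement (mean ± 1.96 SD) separate
   cardiac-driven peaks (Qc⁺, Qc⁻: extremes of the mean curve) from
   breath-driven peaks (Qb⁺, Qb⁻: LOA excursions beyond those extremes),
   plus stroke volume, net flow, and the cardiac/breathing periods.

3. **ΔP = R·Q.** Combining both gives cardiac- and breath-driven pressure
   differences (ΔPc±, ΔPb±, peak-to-peak values in Pa and mmHg, the
   ΔPb/ΔPc ratio) and the along-length pressure-gradient curve.

Because no public datasets exist for this pipeline, the package ships a
first-class synthesis module: curved-tube morphological phantoms with exact
in-plane partial volume and an analytic resistance oracle, and velocity
phantoms with a two-harmonic cardiac waveform, respiratory amplitude/
baseline modulation, static offsets, aliased arterial disks and Gaussian
noise — every stage is testable against known ground truth.

## Worked example

```r
library(aqueduct)

# morphological phantom with known analytic resistance
spec  <- geometry_spec(radius_stenosis(), length = 16)
ph    <- make_phantom_volume(spec)
lm    <- phantom_landmarks(ph$truth)
model <- run_morpho(ph$volume, lm, slice_indices = c(1, 2, 3),
                    verbose = FALSE)
model
#> Aqueduct finite-element model
#>   elements retained : 94 of 100 (95% resistance endpoint)
#>   R                 : 25.0 mPa·s/mm³
#>   L / Ls / L-defined: 14.9 / 14.2 / 15.8 mm (L/Ls = 1.045)
#>   D-mean / D-min    : 2.08 / 1.66 mm
analytic_resistance(spec, s_max = model$L)   # oracle: 24.84 (error +0.6%)

# phase-contrast phantom and flow decomposition
fs <- flow_spec(noise_sd = 2, seed = 1)
fr <- run_flow(make_phantom_series(fs)$series, verbose = FALSE)
fr$metrics
#> Aqueduct flow metrics
#>   Qc+ / Qc- / Qc : 172.3 / 230.9 / 201.6 mm³/s
#>   Qb+ / Qb- / Qb : 123.3 / 125.2 / 124.3 mm³/s
#>   SV             : 52.0 mm³
#>   Q-net          : 0.21 mm³/s
#>   Tc / Tb        : 0.85 / 4.41 s
#>   D-PC           : 4.51 mm

# trans-aqueductal pressure differences
run_deltap(model, fr, verbose = FALSE)$pressure
#> Trans-aqueductal pressure differences
#>   dPc+ / dPc- / dPc : 4.31 / 5.77 / 5.04 Pa
#>   dPb+ / dPb- / dPb : 3.08 / 3.13 / 3.11 Pa
#>   peak-to-peak cardiac: 10.1 Pa (0.08 mmHg)
#>   peak-to-peak breath : 6.2 Pa (0.05 mmHg)
#>   dPb/dPc             : 62 %
```

The recovered resistance sits within a few percent of the quadrature
oracle; cardiac and breathing flow peaks match the generator's ground truth
within the stated tolerances (5% and 15%); the pressure report multiplies
them through ΔP = R·Q.

A thin command-line front end over the same functions lives at
`inst/cli/aqueduct.R` (subcommands `morpho`, `flow`, `deltap`, `simulate`;
NIfTI in, JSON/CSV/txt reports out).

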