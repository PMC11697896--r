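---
title: "Quantifying trans-aqueductal pressure differences: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying trans-aqueductal pressure differences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(aqueduct)
```

## The physical model

CSF flow through the aqueduct of Sylvius is slow, laminar and
viscosity-dominated: Reynolds numbers stay far below the turbulent
transition and Womersley numbers are typically 2–5, so a quasi-steady
Poiseuille description is a reasonable first-order model. The aqueduct is
treated as a gently curved tube of circular cross-section whose diameter
varies along its length. Discretising the centerline into elements of arc
length ΔL and local diameter D, each element contributes

> R = 128 µ ΔL / (π D⁴)

and the total resistance is the sum over elements. With µ in mPa·s and
lengths in mm, R carries the unit mPa·s/mm³, flow Q is in mm³/s, and the
product ΔP = R·Q is in mPa — divided by 1000 and reported in Pa (and
optionally mmHg, 1 mmHg = 133.322 Pa). The package works in this
mm–second–mPa system throughout and converts to SI only inside the
dimensionless numbers:

* Womersley number Wo = (D/2)·√(ω·ρ/µ) with ω = 2π / cardiac period;
* Reynolds number Re = ρ·v·D/µ with v the *mean cross-sectional velocity*
  Q/(πD²/4). The choice of mean rather than centerline velocity is a
  deliberate one — only a flow rate, not a velocity profile, is available
  at this point in the pipeline; for a parabolic profile the centerline
  value would simply be twice ours.

Defaults: µ = 0.71 mPa·s (water at 36 °C), ρ = 1000 kg/m³.

The model deliberately omits unsteady inertial terms. At Wo ≈ 3 viscous
forces dominate but inertia is not strictly zero, so the cardiac-driven ΔP
is a mild underestimate; a Navier–Stokes treatment is out of scope here.

## From a morphological volume to R

The measurement chain is: maximum-intensity projection over 2–3 operator-
selected sagittal slices → bilinear resampling to an isotropic 0.03 mm
working grid → binarization → centerline → element diameters → resistance
profile. The operator supplies four landmarks: a line across the lumen at
its narrowest point, an optional exclusion polygon (e.g. cerebellar CSF
pools touching the aqueduct), and the start and end points. All
coordinates are physical (mm); pixel i of a grid with spacing h sits at
i·h, i counted from 0, and the JSON sidecar stores 0-based pixel indices
with an explicit `"indexing"` field.

**Binarization threshold.** The drawn line is sampled at one working pixel
per step (bilinear). The maximum of the absolute first difference locates
the lumen edge; ties are broken toward the first sample along the line. The
*threshold intensity*, however, is taken as the half-height of that edge:
the mean of the two plateau medians found by walking outward from the
high-gradient run (gradient below 5% of its peak, up to 25 samples,
stopping at the next edge). The reason is quantitative: after bilinear
resampling, the first-difference sequence is piecewise constant between
acquisition-pixel nodes, so the intensity *at* the maximum-gradient sample
can sit anywhere on the partial-volume ramp depending on where the edge
falls relative to the 0.6 mm acquisition grid. Because the binarization
contour is the iso-intensity line at the threshold, each intensity unit of
threshold error displaces the measured boundary by ~7 µm on every side and
R scales with D⁻⁴ — a mid-ramp threshold is the difference between a ~2%
and a ~30% resistance error. The half-height rule equals the
maximum-gradient intensity for an ideal symmetric edge and degrades
gracefully: on a profile that is one global ramp (no plateaus) it falls
back to the literal first maximum-gradient sample.

**Centerline.** The lumen is restricted to the connected component
containing the start point; start/end points may be snapped onto it from up
to 5 working pixels away. A shortest path over lumen pixels with per-pixel
cost 1/(1 + d²) (d the Euclidean distance transform) guarantees start-end
connectivity while hugging the medial ridge. Two refinement passes then
move each path point to the midpoint of its perpendicular boundary chord —
a plain shortest path cuts the inside of bends slightly — and a smoothing
spline in arc length (one degree of freedom per 1.25 mm) removes the
residual chord-phase wobble without the end-shortening a wide moving
average would cause.

**Elements.** The path is partitioned into `n_elements` (default 100)
segments of equal arc length. Each diameter is the perpendicular chord
through the segment midpoint between the two sub-pixel boundary crossings
(linear interpolation of the binary edge at quarter-pixel steps). The
per-element `angle` is the tangent direction against the image x-axis — the
natural unambiguous reference on the projection. A chord that fails to hit
the boundary within 6 mm (a hole punched by an exclusion mask) aborts with
the element index named.

**95% endpoint.** The entrance to the 4th ventricle flares and contributes
almost nothing to the resistance, which makes a manually placed distal
endpoint the largest source of inter-operator variance in L. The model
therefore trims the distal end at the first element where the cumulative
resistance reaches 95% of the total; the crossing element is retained in
full. The start point is never trimmed. Reported alongside: the retained
path length L, the straight-line distance Ls (so L/Ls ≥ 1 measures
tortuosity), the full operator-defined length, D-mean, D-min, the mean
Womersley number and the peak Reynolds number over retained elements.

## From a velocity series to the flow decomposition

The ungated series (default 300 frames at 87 ms, 2 × 2 mm² pixels, venc
100 mm/s, positive = toward the 3rd ventricle) is processed in five steps.

1. **ROI detection.** Per pixel, the fraction of temporal spectral power
   (DC excluded) inside the cardiac band (default 0.7–2.5 Hz, bracketing
   cardiac periods 0.4–1.4 s) is computed; pixels above a threshold are
   grouped and the connected component nearest the seed (image centre by
   default) becomes the ROI. The threshold default is a robust outlier
   rule, median + 6·MAD of the fraction map: the aqueduct occupies well
   under 1% of the plane, and balanced histogram criteria such as Otsu then
   split the *background* distribution rather than isolating the target
   (Otsu remains available as an option, as does a manual override mask —
   the equivalent of the manual ROI correction any operator tool offers).
   The ROI's equivalent diameter 2·√(area/π) is reported as D-PC; with
   2 mm pixels it substantially overestimates the true lumen and is kept
   for comparison only, never used in the resistance.
2. **De-aliasing.** Velocities beyond ±venc wrap by multiples of 2·venc.
   Scanning each pixel's time course forward, any jump larger than venc is
   corrected by the multiple of 2·venc that minimises it — exact whenever
   the true inter-sample change stays below venc, and a no-op on clean
   data. Spatial unwrapping is out of scope; aliased artery *centres* are
   tolerated because only artery edges are ever used (phase detection).
3. **Background correction.** Stationary tissue is taken from a 3–10 pixel
   annulus around the ROI: pixels below the cardiac-power threshold whose
   temporal SD lies in the annulus's lowest quartile. Their spatio-temporal
   mean velocity becomes the new zero. If the annulus yields nothing, the
   lowest-SD decile of the whole image is used, with a warning. A constant
   offset is removed exactly.
4. **Cycle segmentation.** Q(t) = Σ v·pixel-area over the ROI. The cardiac
   period estimate comes from the curve's cardiac-band spectral peak
   (quadratically interpolated); cut points are the per-cycle flow minima
   (one per 0.8-period window, successive cuts forced into 0.6–1.4
   periods), refined to sub-frame precision by a quadratic fit through the
   three samples around each minimum. The refinement matters: at 87 ms per
   frame on a 0.85 s cycle, ±1 frame of cut jitter smears the ensemble
   peak by several percent. Partial first/last segments are discarded; at
   least 3 complete cycles are required.
5. **Ensemble and LOA.** Every cycle is cubic-spline resampled onto 32
   equally spaced phases of its own duration; the mean curve, the
   pointwise SD (denominator k−1, cycles weighted equally regardless of
   duration) and the limits of agreement mean ± 1.96·SD follow.

The decomposition reads: Qc⁺ = max(mean curve), Qc⁻ = −min(mean curve);
Qb⁺ = max(upper LOA) − Qc⁺ and Qb⁻ = −min(lower LOA) − Qc⁻, i.e. the
*global* LOA extremes rather than the LOA–mean gap at the mean curve's
extremal phase — the two coincide when breathing modulates amplitude, and
the global reading is the more direct transcription of "excursion beyond
the extremes". Qc and Qb are the directional averages; stroke volume is
the mean of the positive and negative lobes of the mean cycle; Q-net is
the time average of the *reconstructed* cycle (not of the raw curve, whose
incomplete breathing windows bias it); Tb is the respiratory-band
(0.1–0.5 Hz) spectral peak of the continuous curve — no breathing sensor
is needed. The systole/diastole split ensemble-averages an artery-edge
curve over the same cuts; systole runs from the steepest upslope to the
next zero crossing of the derivative (the waveform peak), and the aqueduct
mean curve is integrated over each phase.

## Pressure differences

Each of Qc±/Qb± is multiplied by the trimmed R: ΔPc±, ΔPb± in Pa,
peak-to-peak sums, mmHg mirrors, and ΔPb/ΔPc in percent (computed per
subject; since R is fixed per subject the ratio equals Qb/Qc). The
along-length gradient curve evaluates cumulative_R(s)·Q at every element
boundary, by default at Qc⁺; it is non-decreasing and ends exactly at
R·Q/1000.

## What the phantoms emulate — and what they do not

**Morphological phantoms** are planar tubes with parametric radius
profiles (uniform, linear taper, Gaussian stenosis, distal flare), lengths
and diameters drawn from the healthy-adult ranges (L ≈ 10–24 mm, D ≈
1.5–2.5 mm, L/Ls ≈ 1.05), rendered at the acquisition geometry
(0.6 × 0.6 × 1.2 mm³) with lumen 100 / background 10 and optional Rician
noise. In-plane partial volume is exact: silhouette coverage fractions are
computed on a 0.03 mm subgrid and averaged per pixel. Through-slice
partial volume is *idealised*: the tube plane is assumed centred in and
fully captured by the MIP slab, so the projection equals the tube
silhouette, and neighbouring slices carry a dimmed copy only to exercise
the MIP semantics. Real acquisitions violate this — averaging a circular
cross-section across a 1.2 mm slice erodes the projected edge by tens of
µm per side — so passing phantom tests demonstrates the fidelity of the
measurement chain, not freedom from through-plane bias on real data. For
the same reason the default stenosis keeps its waist at ≈1.7 mm (≈2.8
in-plane voxels): below that the lumen plateau never reaches full
intensity within a pixel, the half-height threshold becomes
under-determined, and *no* threshold rule operating on the projection can
recover the true width — an information limit of the acquisition that
affects real sub-millimetre aqueducts equally. The analytic oracle is the
trapezoidal integral of 128µ/(π·D(s)⁴) at 10⁵ points; pipeline accuracy is
always judged against the oracle integrated over the same retained extent
as the trimmed model, so the deliberate 95% trim is not counted as error.

**Velocity phantoms** lay a parabolic profile over a pixelated disk and
scale it so the pixel-area-weighted sum reproduces the model flow exactly:
Q(t) = (1 + m·sin(2πt/Tb))·c(t) + b·sin(2πt/Tb), with c(t) a two-harmonic
cardiac waveform (fast systolic peak, deeper slower trough; a pure
sinusoid is available for closed-form tests), Tc = 0.85 s, Tb = 4.1 s,
peak ≈ 170 mm³/s. The defaults m = 0.45, b = 13.5 mm³/s make the two
breath-driven peaks nearly equal at ≈125 mm³/s (≈65% of Qc), with the
amplitude-scaling mechanism dominant; both mechanisms the LOA
decomposition is meant to capture are present. Ground truth for Qb is
recorded in the quantity's own LOA definition: sinusoidal modulation gives
per-cycle extreme deviations with SD (m·Qpeak + b)/√2, hence true
Qb± = 1.96·(m·Q± + b)/√2. Static offsets, supra-venc arterial disks
(wrapped into (−venc, venc]) and Gaussian velocity noise complete the
model. Not emulated: eddy-current gradients beyond a constant offset,
partial-volume velocity underestimation at the lumen rim, k-space physics,
and any anatomy around the aqueduct.

## Problem sizes, tolerances and determinism

The validation suite runs three noise-free phantoms end-to-end (recovered
R within 5% of the oracle; 100-element discretization of analytic
geometries within 1%), ten 300-frame velocity series at flow-curve SNR 10
(noise SD = Qpeak/(SNR·pixel-area·√n_ROI); Tc within 2%, Qc within 5%, Qb
within 15% of generated values), a 200-cycle LOA coverage check (95 ± 2%),
exact de-aliasing round trips and offset removal, and the structural
invariants (resistance additivity, D⁻⁴ scaling, LOA ordering, monotone
pressure gradient, the 95%-trim bracket). These sizes keep the full suite
under a minute on a single core while leaving every tolerance with a
comfortable margin. All generators are deterministic given their seed; the
noise-free morphology pipeline is deterministic outright. The
single-series |Q-net| bound of 2 mm³/s is asserted on the noise-free
series; under noise the estimator's own spread (~1 mm³/s) plus the
partial-breathing-window residual make it a bound on the mean across
seeds, which is what the suite checks.

## Known limitations

* Poiseuille neglects inertia; ΔPc is underestimated at higher Womersley
  numbers.
* The cross-section is assumed circular; elliptical lumens bias D and
  hence R, and only a 3D treatment could resolve them.
* Projection-based diameters inherit through-plane partial volume; lumens
  narrower than ~3 in-plane voxels are at the resolvability limit.
* D-PC from 2 mm phase-contrast pixels overestimates the lumen area
  substantially and is reported for reference only.
* ΔP is a surrogate for — not the equal of — transmantle pressure.
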