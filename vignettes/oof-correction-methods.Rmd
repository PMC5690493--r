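---
title: "Out-of-field response correction for measurement-guided dose reconstruction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Out-of-field response correction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oofrecon)
```

## The problem

Cylindrical diode arrays used for IMRT/VMAT patient-specific QA are not
water-equivalent: outside the direct beam, where the photon spectrum softens,
diodes over-respond relative to an ion chamber.  Measurement-guided 3D dose
reconstruction engines absorb this overresponse into their beam models during
commissioning.  When a hardware redesign reduces the amount of high-Z material
near the diodes, the out-of-field (OOF) overresponse drops — the measurement
gets *better* — but the beam model now over-compensates, and reconstructed
dose comes out systematically low in collimated regions.  Rather than
recommissioning a model library per hardware revision, a single user-set
correction factor can dampen the compensation, adding small amounts of dose
back, but only where the beam was blocked by MLC leaves or jaws.

This package implements that correction and everything needed to validate and
tune it on synthetic data: BEV fluence accumulation, the composite correction
mask, its application to 3D subbeam dose, gamma analysis, TG-119-style
confidence limits, a toy dose engine with a simulated diode response, and the
correction-factor scan.

## The correction model

A beam is delivered as a sequence of control points; between two meterset
values it forms a *subbeam*.  For each subbeam the package accumulates, on a
regular beam's-eye-view (BEV) grid at the isocenter plane, the MU-weighted
exposure of every pixel:

* a pixel inside the momentary aperture contributes its full MU,
* a pixel under an MLC leaf contributes `MU × T_mlc`,
* a pixel under a jaw contributes `MU × T_jaw` (jaw blocking takes
  precedence in classification).

This is the *uncorrected fluence* `U(x, y)`.  The *corrected fluence* adds,
for every MU interval in which the pixel is collimated, the adjustment
`(OOFCF − 1) × EDF`, where OOFCF is the user's nominal out-of-field
correction factor (1.0 = no change) and EDF a small per-energy scalar
(~0.01–0.025, increasing with energy) that keeps a single OOFCF usable across
energies.  The *composite OOF correction mask* is the pixel-wise ratio of the
MU-integrated corrected to uncorrected fluence:

```
mask(x, y) = [U(x, y) + (OOFCF − 1) · EDF · B(x, y)] / U(x, y)
```

with `B(x, y)` the collimated-MU integral.  The mask equals 1 exactly where
the pixel was open for the whole subbeam and reaches
`(T + (OOFCF − 1)·EDF) / T` where it was blocked throughout.  Because the
correction is affine in OOFCF, the package caches `U` and `B` once per
subbeam and evaluates any factor exactly — the tuning scan exploits this.

The corrected subbeam dose at a phantom point is the uncorrected dose times
the mask value at the point's divergent projection to BEV.  The correction is
constant over depth along each ray, but is tapered to unity at the curved
entry and exit surfaces of the detector-array cylinder: the applied factor is
`1 + w · (mask − 1)` with `w` ramping linearly from 0 at the surface to 1 at
`taper_distance` (default 10 mm) inside, measured along the ray.  The taper
shape and extent are a design choice of this package: the commercial
behaviour is described only as a taper to unity at the array surfaces, so a
linear ramp over a configurable distance is the simplest realization, and
`taper_distance = 0` recovers an untapered correction.  The taper operates on
per-ray path length into the cylinder rather than absolute depth, again a
choice where either reading is defensible.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `nominal_oofcf` | 1.0 | user correction factor; 1.17 is the maximum measured old/new response ratio and the default cap |
| `edf` | 0.02 | energy dependence factor (dimensionless) |
| `mlc_transmission` | 0.02 | MLC transmission fraction |
| `jaw_transmission` | 0.005 | jaw transmission fraction |
| BEV resolution | 1 mm | mask pixel pitch at isocenter |
| substep cap | 0.25 MU | MU sub-interval for aperture sampling |
| `taper_distance` | 10 mm | surface taper ramp length |
| array radius | 104 mm | detector cylinder of the default geometry |

## Numerical choices

**Pixel classification** is a center-point test (no area weighting): the
fluence definition is binary in/out plus transmission, and partial-pixel
effects sit below the 1 mm default resolution.

**Substep integration** samples the aperture at the midpoint meterset of
equal MU sub-intervals.  For linear leaf motion the open/blocked indicator of
a pixel is a step function of MU, so the integration error is a quantization
of the pixel's open fraction `f` by up to `1/(2n)` for `n` substeps.  The
mask is most sensitive to this near the blocked extreme:
`|dmask/df| = (OOFCF−1)·EDF / (f + (1−f)T)²`, which reaches
`(OOFCF−1)·EDF/T²` (≈ 8.5 at the defaults) as `f → 0`.  Consequently
per-pixel mask agreement between coarse and fine substeppings is bounded by
`8.5/(2n)`, *not* by a second-order term — a property the test suite verifies
explicitly, together with exact agreement between the package integrator and
an independent brute-force oracle at matched discretization.  Users needing
tighter masks near leaf tips should lower the substep MU cap.

**Mask sampling** is bilinear in BEV, voxels projected individually along
divergent rays; voxels projecting outside the mask footprint are left
unchanged and counted.

**Gamma analysis** follows the standard formulation: for each reference point
above the low-dose threshold (default 10% of the reference maximum),
`γ = min over the neighbourhood of sqrt((Δr/DTA)² + (ΔD/tol)²)`, with the
tolerance a percent of the reference maximum (global) or of the local
reference dose (local); a point passes at `γ ≤ 1` inclusively.  The evaluated
distribution is resampled trilinearly on a lattice of pitch
`interp_fraction × DTA` (default 1/10); setting `interp_fraction = NULL`
restricts candidates to the evaluated grid's own voxel centers, which is the
mode used for brute-force equivalence testing.  The search starts within
`search_radius_factor × DTA` and expands automatically whenever the running
minimum could still be improved by more distant candidates, so the reported
gamma is a global minimum rather than a window-limited one.  The median dose
difference is the median signed local percent difference over the same
above-threshold set; mirroring the gamma threshold keeps the two statistics
on one population.

**Summary statistics** use the sample (n−1) standard deviation — verified to
reproduce the published table SDs, which the population form does not — and
half-away-from-zero rounding to one decimal for table reproduction.
Confidence limits are `mean ± 1.96·SD` (two-sided) and `mean − 1.96·SD`
(one-sided pass-rate bound); the published one-sided bounds apply the
arithmetic to the one-decimal summary rows, so the reproduction does the
same.  Both sign conventions of the one-sided limit are exposed, since the
reference usage alternates between "shortfall from 100%" and "at least X%
pass".

## The synthetic study conditions

The simulator exists so the whole pipeline can be exercised without measured
data; its defaults *are* the study conditions and are not tuned per test.

* **Plans**: static open fields (2 control points), sliding-window sweeps,
  arcs at a control-point increment (181 control points for a 2° full arc),
  narrow OOF-test apertures (0.5–3 cm wide, measurement point 1–2 cm outside
  the field), and random dynamic beams for property tests.  All are
  deterministic given a seed.
* **Toy dose engine**: `ΔMU × (Gy/MU) × inverse-square × exp(−μ·WEPL)`, with
  a scatter floor plus transmission for collimated rays, on a cylindrical
  phantom of relative density 1.15.  The attenuation coefficient default
  (0.00405/mm water-equivalent) is calibrated so the exit dose of the
  266 mm phantom is one quarter of the entrance dose, matching the reported
  entrance/exit ratio of the plugged array.  The engine has no head scatter,
  no penumbra, no buildup — it is a pipeline exerciser, not a dose model.
* **Diode response**: multiplicative, independent perturbations — per-segment
  low-MU nonlinearity (−2.8% at 2 MU under default acquisition settings,
  roughly halved with long integration), dose-per-pulse via SDD (1.012 to
  0.992 over 746–1196 mm for 6X, unity at the 896 mm calibration SDD),
  repetition rate (0.978 at 5 MU/min, unity at 400 MU/min), and an OOF
  overresponse factor applied to the collimated dose component only (1.17 is
  the maximum measured old/new ratio).  Only the anchors marked `printed` in
  the packaged CSVs are measured values; intermediate points are monotone
  (Fritsch–Carlson) interpolation and marked `synthetic-fill`, so recovering
  a curve *between* anchors tests interpolation, not physics.  No cross-terms
  are modeled because the reference characterization reports each effect as
  a separately normalized ratio.

Passing closed-loop tests on these conditions shows the machinery is
self-consistent and the estimator unbiased under the modeled effects; it
does not validate the correction against real accelerator data, real leaf
ends (tongue-and-groove, rounded tips, interleaf leakage are all absent), or
real detector physics.

## Tuning the correction factor

`fit_oofcf()` scans a factor grid (default 1.00–1.25, step 0.01): for each
value the masks are rebuilt, subbeam doses corrected and accumulated, and
the total compared to a reference distribution by 2% local / 2 mm gamma and
the median dose difference.  The selected factor minimizes the mean absolute
median dose difference — pass rates nearly plateau around the optimum, so
they are reported as a diagnostic rather than optimized — with ties resolved
to the smaller factor and the result clamped to a cap (default 1.17, the
maximum measured response ratio; there is no reason to correct beyond what
was measured).  When several comparisons are supplied (e.g. both delivery
techniques of one dataset), the objective averages their absolute medians.

The closed-loop validation builds the reference by applying the correction
with a known true ratio `R ∈ {1.05, 1.10, 1.17}` and checks the scan
minimizer lands within one grid step of `R` — exact here, because the
corrected dose is affine in the factor.  The acceptance problem sizes are a
7-control-point 40 mm arc, a 19×19×7 voxel lattice at 10 mm, and 51
biplanar reference points; these were chosen as the smallest geometry in
which most reference detectors spend part of the arc out of field, which is
what gives the median objective its sensitivity (detectors that never leave
the open field receive no correction and pin the median at zero).

## Known limitations

* The EDF is a per-energy configuration scalar; its derivation from
  dose-per-pulse model parameters in the commercial implementation is not
  public.
* The subbeam time resolution of the commercial software is unspecified;
  segmentation defaults to one subbeam per control-point interval with an
  MU-capped splitting rule, flagged in the configuration.
* Plan I/O covers the package's structured-text dialect; couch and
  collimator rotation, wedges and electron plans are out of scope.
* Gamma search behaviour of commercial comparison software (evaluated-grid
  interpolation, search radius) is unknown; both are configuration-exposed
  here.
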