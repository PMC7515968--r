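---
title: "Quantifying perivascular tracer accumulation from two-channel imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying perivascular tracer accumulation from two-channel imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perivasc)
```

## The measurement problem

In vivo two-photon experiments on cortical amyloid clearance inject a
fluorescently labelled soluble tracer (an A&beta;40 analog, green channel)
into the superficial cortex while the blood plasma is labelled with an
intravascular dye (an SR101 analog, red channel).  The tracer diffuses
through the neuropil and drains along vessel walls; around a subset of
vessels it *compacts* into a thin abluminal sleeve.  The scientific
quantity is the fraction of vessels carrying such perivascular deposits,
how that fraction evolves over the ~40 min of imaging, and how it differs
between treatment groups.

Human raters decide vessel positivity by eye.  `perivasc` operationalises
the decision with a line-profile statistic so that it is reproducible and
testable:

1. a 100 µm line is placed across the vessel (annotation-driven, as in
   the manual workflow);
2. the lumen edge is detected on the red channel as the half-maximum
   crossing of the lumen plateau, with local background subtraction; the
   edge defines 0 µm of an *abluminal* axis on each side;
3. the mean green intensity over the first 3 µm outside the edge
   (`mean_near`) is contrasted with the mean over the next 7 µm
   (`mean_far`).  Tracer compacted on the wall raises the near window
   only; diffuse parenchymal tracer raises both.

The package adds everything needed to make that statistic a defensible
instrument: a synthetic image generator with known ground truth, vessel
diameter and time-course metrics, distance stratification, wall
morphometry for labelled electron-microscopy-style masks, and the group
statistics used downstream.

## The per-vessel decision rule

The source experiments validate the near/far contrast only at group level
(positive vs negative vessel groups); per-vessel positivity there remains
an expert judgement.  A reusable pipeline needs an explicit per-vessel
rule, so one is defined here and treated as the operational definition of
"positive":

* **z-score mode (default).** `contrast = mean_near − mean_far` is
  standardised by a local noise scale and a vessel is positive when the
  mean of its per-side z values reaches `z_threshold = 3`.  The noise
  scale is the robust SD (`1.4826·MAD`) of the green samples 15–25 µm
  out: beyond the ring and the steepest diffusion gradient, but still
  local.  A z of 3 keeps the per-vessel false-positive rate well under
  1% while amplitudes ~10× the noise give z near 8–9.
* **ratio mode** (`mean_near / max(mean_far, noise)` ≥ 1.2) and
  **group-test mode** (one-sided paired near-vs-far comparison across
  repeated frames at `alpha = 0.01`) are provided for sensitivity
  analyses.

Two sides of one lumen are treated as two measurements of one vessel and
averaged, never OR-ed.  Vessels whose profile cannot be measured — the
line leaves the field, no lumen signal, a truncated side, or a second
lumen intruding into the analysis span ("unclear profile") — are
*excluded*: they appear in the outputs with a reason but enter neither
numerator nor denominator of positive fractions.  Truncated or unclear
sides are flagged (`usable = FALSE`) rather than thrown as errors so the
bookkeeping survives batch runs.

## What the simulator emulates

`sim_config()` defaults encode the imaging conditions of the emulated
experiment:

| parameter | default | meaning |
|---|---|---|
| `field_size_um` | 425.10 | square field of view, µm |
| `image_px` | 512 | grid, i.e. ≈0.830 µm/px |
| `frame_interval_min`, `total_min` | 5, 40 | frames at t = 0, 5, …, 40 min |
| `n_vessels` | 50 | vessels per field (the order of the per-animal counts analysed in vivo) |
| `vessel_diameter_range_um` | 5–13 | spans the reported positive/negative vessel diameter means |
| `p_positive` | 0.3 | treated-like positivity rate |
| `diffusion_coeff_um2_per_min` | 10 | free 2-D diffusion of the tracer bolus |
| `injected_mass` | 25000 | sets the bolus peak to ~40 intensity units at t = 5 min |
| `ring_amplitude`, `ring_width_um` | 20, 3 | abluminal sleeve; 10× the background noise SD |
| `rise/plateau/decay_min` | 15/10/15 | trapezoidal ring time course |
| `lumen_intensity` | 100 | red plateau inside lumens |
| `noise_gain`, `read_noise_sd` | 1, 2 | Poisson×gain + Gaussian detector model |

Choices worth spelling out:

* **Single 2-D plane.**  The classifying statistic lives on a 2-D line
  profile, so one optical section is the simulated unit; no z-stacks.
* **Diffusion background.**  The tracer bolus is the free-space 2-D heat
  kernel `C(r,t) = M/(4πDt)·exp(−r²/4Dt)`: no uptake or boundary terms.
  Its role is to stress the classifier with a realistic radial gradient,
  not to model clearance physics.
* **Ring time course.**  A trapezoid (linear rise over 15 min, 10 min
  plateau, linear decay over 15 min) is the simplest shape matching the
  reported dynamics of positivity after a small-volume injection.
* **Channels.**  The red lumen disks are rendered with a fixed 0.5 µm
  Gaussian edge (an erf radial profile) whose half-maximum crossing sits
  exactly at the true radius, so the FWHM diameter convention is
  self-consistent.  Green is excluded from lumens (the tracer is
  extravascular); rings are hard annuli `(R, R+3]` µm.
* **Detector noise.**  `gain·Poisson(I/gain) + N(0, read)` clipped at
  zero.  The emulated instrument's detector is uncharacterised, so both
  parameters are exposed; `noise_gain = 0` gives pure Gaussian noise with
  an exactly known scale, which the calibration runs use.
* **Vessel placement.**  Rejection sampling with a minimum lumen-surface
  separation, `min_separation_um = 13` (ring width + the 10 µm analysis
  span).  This guarantees every annotated vessel is analyzable by
  construction — no neighbouring lumen or ring inside another vessel's
  windows — which emulates the *selected*, clearly profiled vessels of
  the manual protocol; real cortical capillary spacing (~50 µm) is far
  sparser than even this packing.  Centres also stay `edge_margin_um =
  51` µm from the border so a default measuring line never exits the
  field.

What the generator deliberately does **not** emulate: hemodynamic
diameter fluctuation (reported absent in vivo), photobleaching, arterial
vs venous identity, vessel curvature (lumens are disks), motion
artefacts, and 3-D geometry.  Passing tests therefore demonstrate the
correctness and calibration of the *measurement machinery* under
controlled conditions, not robustness to every nuisance of real
microscopy.

## Numerical conventions

* Coordinates are continuous µm; the centre of pixel (i, j), 1-based,
  sits at ((j−0.5)·px, (i−0.5)·px); x runs along columns, y down rows.
  All µm↔px conversion goes through one internal helper.
* Profiles sample both channels by bilinear interpolation at 0.25 µm
  steps (≈⅓ pixel at the default grid); the sampling step must not
  exceed the pixel size.  Window means change by <1% when the step is
  halved, so the windows are effectively continuous.
* Analysis windows are half-open: near `(0, 3]`, far `(3, 10]` µm.
* Edge detection walks outward from the red plateau peak, restricted to
  ±15 µm around the line centre — the annotated lumen is at the centre
  by construction, and the restriction keeps a second vessel crossed
  further along the line from hijacking the peak.  The crossing is
  linearly interpolated between samples; per-side background is the
  median of the outer 20% of samples.
* The trapezoid, the heat kernel, and the ring annulus are evaluated
  analytically at pixel centres; nothing is rasterised at lower
  precision and re-smoothed.
* All randomness flows from `seed` through per-purpose derived streams
  (placement, per-frame noise), so datasets are reproducible
  byte-for-byte and frames are independent but deterministic.

## Verification strategy and problem sizes

The test suite checks closed forms first (heat-kernel origin value, mass
conservation, the `C(20 µm)/C(0) = e⁻¹` ratio, trapezoid leg values,
top-hat and erf-edge crossings), then property-style invariants
(mirror/rotation symmetry of profiles, affine invariance of edge
detection, monotone and exactly linear amplitude response, exclusion
bookkeeping, Tukey monotonicity), and finally pipeline-level acceptance
runs at the study conditions: 200 vessels for classifier validity, 1000
diffusion-only null vessels for false-positive calibration, diameters
5–13 µm for geometry recovery, 200 repeats of a 5+5-animal two-group
design for effect detection, and 10⁴ null repeats for t-test
calibration.  The window-recovery oracle uses a 0.1 µm/px rendering so
that pixelation (which at the default 0.83 µm/px costs ~6% of the ring
amplitude in the near window) does not confound the 0.5 µm optical edge
tolerance; classification accuracy is always assessed at the default
resolution.

One design-level caveat is worth stating plainly: with 5 animals × 50
vessels per group and true rates 8% vs 30%, the per-animal binomial
sampling alone caps the power of a two-sided Welch test at α = 0.001
near 65% — no classifier, however perfect, can push the rejection rate
of that design to 90%.  The effect-detection acceptance run reports the
measured power honestly rather than redefining the design to reach a
preset figure.

## Morphometry

Wall-composition analysis consumes labelled masks (0 background, 1
lumen, 2 endothelium, 3 intramural cell, 4 basement membrane; there is
deliberately no perivascular-space class).  Area fractions are pure
pixel-count arithmetic.  Basement-membrane thickness casts 360 rays from
the lumen centroid and takes the *maximum* per-ray radial run of
membrane lying outward of endothelium/intramural tissue and reaching the
background — "thickest abluminal region" semantics; membranes buried
under other wall tissue are not abluminal and yield a flagged `NA`.
Ray-cast thickness is accurate to about one pixel plus the ray step
(px/4); masks should resolve the membrane with ≥5 pixels across it.

## Group statistics

Two-group comparisons default to Welch's t (the safer reading of an
unspecified "Student t test"; the pooled classic is a flag away),
two-sided, run on *animal means* — frames average into an animal, animals
into a group, never vessels pooled across animals.  Factorial designs
(treatment × injected volume) use `aov` with Tukey HSD on the cell
means; adjusted p-values are never smaller than their unadjusted
counterparts.  Significance stars follow the strict `*`/`**`/`***`
thresholds at 0.05/0.01/0.001, and report formatting is `mean ± SD` to
three decimals.

## Known limitations

* The per-vessel rule is a construction of this package; on real data it
  should be validated against expert calls before being trusted for
  effect sizes (the colocalization coefficient is provided as a second,
  independent reading).
* Diameters use the FWHM convention; instruments or raters using
  full-width-at-background will read systematically larger values.
* The simulator's nuisance realism is limited (see above), so measured
  sensitivity/specificity are upper bounds for real imaging.
* Mapping fluorescence intensity to the labelled masks consumed by the
  morphometry is the user's responsibility; the package measures masks,
  it does not segment.
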