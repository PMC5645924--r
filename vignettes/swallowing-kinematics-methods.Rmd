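---
title: "Methods: anatomical-frame swallowing kinematics, the phantom, and the verification statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: anatomical-frame swallowing kinematics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deglukin)
```

## The measurement model

A videofluoroscopic swallowing study yields a lateral projection video in
which an examiner marks, per frame, the pixel position of each structure of
interest. `deglukin` analyzes those marks under three assumptions:

1. **Planarity.** Swallowing motion of the marked structures is treated as
   two-dimensional, because the fluoroscope projects onto a single lateral
   plane. Out-of-plane motion appears as foreshortening and is not
   corrected.
2. **A rigid cervical reference.** The segment between the anteroinferior
   vertices of C2 and C4 is treated as rigid within a swallow. The
   anatomical frame is re-derived in every frame from those two marks, so
   whole-head translation and rotation cancel exactly (a property the test
   suite checks to 1e-9 mm by applying random rigid motions to all marks).
   What does *not* cancel is independent error in the C2/C4 marks
   themselves: jitter in the landmarks tilts the frame and leaks into every
   transformed coordinate, which is why the C2–C4 marks deserve the most
   care during digitization.
3. **Uniform sampling.** Frames arrive at a constant rate (`fps`), so the
   sampling interval is Δt = 1/fps and velocities can use fixed-stencil
   finite differences. At the common 30 frames/s the inter-frame interval
   is 0.033 s.

The pixel-to-anatomical transform composes four steps: flip the v axis
(image rows grow downward), change basis into the per-frame C2–C4 frame,
negate the x component (the anatomical horizontal axis points to the image
*left*, i.e. anteriorly, opposite to the usual convention), and scale by
the calibration factor. Under it, C4 maps to the origin and C2 to
(0, s·‖C2−C4‖) by construction.

### Calibration

The scale factor `s` (mm/pixel) is the ratio of the true length of a
reference object to its pixel length. Defaults follow common practice: a
coin of 24.0 mm diameter, measured in the **first 3 frames** in which both
coin marks are present. The per-frame distances are averaged (mean of
distances, not distance of mean points — the two differ when the coin mark
jitters), and the selection of frames is deterministic so repeated runs
agree byte for byte. One global `s` is used per recording; per-frame
re-calibration drift is not modeled. A zero coin separation in any used
frame aborts with a "degenerate calibration" error rather than producing an
infinite scale.

## Trajectory smoothing

Manual marking adds roughly pixel-scale jitter which finite differencing
amplifies by 1/Δt, so component series are smoothed **before**
differentiation — differentiating raw marks and then smoothing the
velocity would let single-frame outliers contaminate two velocity samples
each. Smoothing is applied to the anatomical-frame component series:
marker x and y for point structures, the tilt-angle series for the
epiglottis (computed from the raw base/tip positions, then smoothed as one
series — smoothing base and tip separately and re-deriving the angle is
not equivariant and can bias the angle near fast rotations), and each UES
margin's x/y before taking their distance.

Methods and their conventions (all length-preserving, NA positions
preserved; NAs are excluded from fits and re-inserted, with surviving
samples keeping their original index positions as the abscissa so a gap is
treated as a real distance, not as adjacency):

- **moving_average** (default, span 5): centered mean; near the edges the
  window shrinks symmetrically to the largest odd width that fits, so the
  endpoints pass through unchanged. This is the edge behavior users of the
  platform this style of analysis grew up on expect, and it is trivially
  oracle-testable.
- **savitzky_golay** (span, degree): local least-squares polynomial
  evaluated at the window center; edge windows are truncated one-sided and
  the local degree is capped at window length − 1. Degree 0 reduces to the
  moving average at interior points; polynomials up to the fit degree are
  reproduced exactly at interior points.
- **lowess / loess / robust_lowess / robust_loess** (span as fraction of
  the series or absolute k ≥ 3): k-nearest-neighbor locally weighted
  regression with tricube weights, local degree 1 (lowess) or 2 (loess).
  Robust variants run a fixed 5 bisquare re-weighting iterations using
  s = median|residual| and weight (1 − (r/6s)²)²₊. Two numerical
  safeguards: neighbor ties are broken toward the earlier index, and if
  robust down-weighting empties a window below degree + 1 usable points the
  fit falls back to the nearest points that still carry positive robust
  weight (on exactly noiseless data the residual median collapses to
  machine zero, which would otherwise zero out every slightly contaminated
  neighbor of an outlier).
- **polynomial** (degree): one global least-squares polynomial over the
  whole series, fitted on an orthogonal basis for stability; degree n − 1
  interpolates, duplicate abscissae are rejected as rank-deficient.

All methods are shift- and positive-scale-equivariant, which the suite
checks for every method; this is the property that guarantees the choice
of displacement origin does not interact with smoothing.

Only the moving-average default span (5) is an established convention; the
other defaults (Savitzky–Golay degree 2, lowess span as given) are package
choices, overridable globally (`smoothing.method`, `smoothing.span`,
`smoothing.degree`) or per structure (`smoothing.hyoid.method = ...`).

## Kinematic parameters

Velocities use the forward/central/backward difference stencil, which is
exact for affine motion everywhere and for quadratic motion at interior
samples; the interior truncation error for smooth motion is bounded by
(Δt²/6)·max|x‴|. Series with interior gaps are split into contiguous
non-NA runs and differentiated per run — no interpolation across gaps,
because a gap usually means the structure was invisible and any
interpolation would be invention.

Per structure:

- **hyoid, larynx, arytenoid** (and mandible/maxilla when marked): signed
  vertical (along C4→C2) and horizontal (anterior-positive) displacement
  from a reference frame, their Euclidean 2D magnitude, and the three
  corresponding velocities (2D velocity is the planar speed
  √(v_x² + v_y²)).
- **epiglottis**: tilt angle of the base→tip vector, reported two ways —
  unsigned from the +y axis in [0°, 180°], and signed from the initial
  orientation in (−180°, 180°], **clockwise positive** in the anatomical
  frame (tilting from upright toward posterior-inferior, the physiological
  folding direction). The sign convention is a package decision, stated
  here rather than inherited. Angular velocity differentiates the
  unwrapped from-initial series so a crossing of ±180° cannot create a
  velocity spike.
- **UES**: per-frame distance between the anterior and posterior margins;
  the reported parameter is the maximum opening distance.
- **bolus**: peak planar speed of the bolus head (one number, not
  per-axis).

Peaks use greatest-magnitude-with-sign for signed components (reported
maxima carry direction) and the plain maximum for magnitude series, with
ties broken toward the earliest frame for determinism. The displacement
reference is the first frame where the structure is marked, unless a
configured motion-start event exists in the event log (both behaviors are
supported; first-frame is the default because an event is not always
recorded).

The two-point representation of the coin, epiglottis and UES (pairs
`coin_a/coin_b`, `epiglottis_base/epiglottis_tip`,
`ues_anterior/ues_posterior`) is a data-model decision: angles and opening
distances require two points. Frame indices are 0-based everywhere (files,
APIs, reported peak frames). Missing markers are represented by absent
rows, never by silently copying the previous frame's positions forward —
an interactive convenience that, in a file format, would be
indistinguishable from real measurements.

## The phantom

Patient VFSS videos cannot be redistributed, so end-to-end validation runs
on a simulated instrument with closed-form ground truth, mirroring the
instrumental models used to validate this class of software:

- a **slider–crank** (in-line): d(θ) = r·cosθ + √(l² − r²·sin²θ),
  θ = θ₀ + ωt, with the analytic velocity used as the velocity reference.
  The slider carries the hyoid marker along the anatomical vertical axis;
  the stroke is 2r.
- a **belt–pulley** with rigid transmission: φ(t) = φ₀ + ratio·ω·t, so the
  follower angle is linear in time and the angular velocity constant. The
  follower rotates the epiglottis base→tip arm.

Defaults (r = 10 mm, l = 50 mm, ω = π rad/s, 30 fps, 2 s, pulley ratio
0.25, 25 mm arm, 4 px/mm) give one full crank cycle, a 20 mm stroke and a
90° sweep — magnitudes in the range of real hyoid excursions and
epiglottic tilts. Marking error is modeled as i.i.d. isotropic Gaussian
pixel noise per marker per frame (σ in px, seeded; the seed is written
into the recording metadata so any file is reproducible). `c2_c4_drift`
applies a sinusoidal rigid motion to the whole scene, which the
anatomical-frame analysis must — and, per the tests, does — cancel.

What the phantom does **not** emulate: fluoroscopic image formation and
its contrast limits, observer-specific marking bias (noise is zero-mean
and isotropic), soft-tissue deformation, bolus flow, and out-of-plane
motion. Passing the phantom suite therefore demonstrates the correctness
of the geometry, calibration, smoothing and differentiation pipeline — not
robustness to the image-quality problems of faint clinical fluoroscopy.

## Verification statistics

The **ICC** is computed from the two-way ANOVA mean squares of an
n-subjects × k-raters table. The published reports of this kind of
software do not name the ICC variant, so both common single-measure forms
are exposed and the choice is explicit in the result object: two-way
random effects, absolute agreement (ICC(2,1)) as the default for
interrater questions — raters are a random sample and systematic offsets
between them should count against agreement — and two-way mixed,
consistency (ICC(3,1)) for intrarater questions. Confidence intervals use
the standard F-based formulas (Satterthwaite degrees of freedom for the
absolute-agreement form). The point estimate is classified with the
conventional thresholds — excellent above 0.75, good from 0.60, moderate
from 0.40, poor below — reading the rule's "greater than 0.75" strictly,
so 0.75 itself is good and the half-open intervals close the gaps the
verbal rule leaves between 0.59/0.60 and 0.74/0.75.

**Pearson r** carries a two-sided p from the t transform on n − 2 degrees
of freedom. **Bland–Altman** agreement uses bias = mean(measured −
reference) and limits bias ± 1.96·SD with the n − 1 denominator; the
per-pair (mean, difference) table is kept for plotting.

A coverage experiment backs the CI implementation: on two-way
random-effects data with known population ICC (subject variance 2, rater
variance 0.1, error 0.9, so ρ = 2/3), the 95% interval covers ρ in ≈95% of
500 replicates at n = 30, k = 2.

## Problem sizes and tolerances

The test suite and the acceptance script run on deliberately small
problems with analytic answers: 61-frame phantom recordings (2 s at
30 fps), a 15-configuration validity sweep spanning 6.22–48.64 mm strokes
and 10°–160° sweeps at σ = 0.5 px, and 500 ICC replicates at n = 30,
k = 2. Geometry and transform identities are asserted at 1e-9 mm,
orthonormality at 1e-12, phantom peak-displacement recovery at 1e-6 mm,
and velocity recovery within the (Δt²/6)·max|d‴| truncation bound computed
from the closed form. These sizes keep the full suite under ten seconds
while every assertion remains a mathematical identity rather than a
regression snapshot.

## Known limitations

- Measurement quality is bounded by marking quality; the package neither
  enhances images nor marks them.
- Velocity accuracy degrades at low frame rates: the truncation bound
  grows with Δt², and fast events (UES opening, epiglottal snap-back) can
  alias at 30 fps.
- The C2–C4 rigidity assumption fails in patients with cervical
  instrumentation or marked spondylosis at those levels.
- The epiglottis from-initial angle depends on the reference frame chosen;
  comparisons across recordings should fix the reference the same way
  (first marked frame or a shared motion-start event).
- ICC values computed under one model (ICC(2,1) vs ICC(3,1)) are not
  comparable across models; the result object records which was used.
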