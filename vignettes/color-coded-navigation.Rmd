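---
title: "Color-coded electromagnetic navigation for mandibular reconstruction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Color-coded electromagnetic navigation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emnav)
```

## The problem

In mandibular reconstruction with free fibula flaps, a graft assembled from
several osteotomized fibular segments must be positioned against the
residual mandible exactly as planned. Misplacement of the reconstructed
condyle or jaw angle causes malocclusion, limited mouth opening and facial
asymmetry. Electromagnetic tracking (EMT) suits this surgical site because
the small coil sensors need no line of sight: one sensor is screwed to the
residual mandible, one to the graft, and a third — the reference sensor — to
the zygomatic bone so that all measurements are invariant to head motion.

`emnav` implements the computational core of such a navigation system:
6-DOF pose algebra, streaming landmark acquisition, paired-point rigid
registration with error metrics, real-time color-coded distance maps
between tracked and planned bone segments, a synthetic phantom simulator
with known ground truth, and the postoperative accuracy statistics used to
compare intraoperative navigation readings against postoperative CBCT.

## Pose algebra and frames

Every rigid transform carries explicit `source_frame` and `target_frame`
labels ("tracker", "reference", "plan", `"sensor:<id>"`), and composition
(`rt_compose`) refuses frame chains that do not match. This is deliberate:
the pipeline constantly mixes tracker-frame sensor poses with
reference-frame measurements and plan-frame geometry, and silent frame
confusion is the classic failure mode of navigation code. Rotations are
stored as unit quaternions (w-first, active, right-handed; the sign
ambiguity is resolved to `w >= 0`). The tracker hardware's own quaternion
convention is not standardized across vendors; the I/O schema documents
ours, and converting vendor streams is the caller's responsibility.

`relative_pose(sensor, reference)` returns
`reference_pose^-1 * sensor_pose`, the sensor pose expressed in the
reference-sensor frame. Any common rigid motion applied to both poses —
the patient's head moving — cancels exactly, which the test suite verifies
on 1,000 random trials. Pose pairs must be synchronous within a tolerance,
5 ms by default (half a 40 Hz sample interval); the tracker's true
inter-sensor skew is hardware-dependent, so the tolerance is configurable.

## Landmark acquisition

A landmark is captured by holding a tracked pointer still: 60 tip points
are collected at 40 Hz (1.5 s) and averaged, which suppresses hand tremble
by roughly `sqrt(60)`. If any sample lands more than 0.5 mm from its
predecessor, the series is discarded and restarted — a slipped probe must
not contaminate the mean. Two boundary choices are not dictated by the rule
itself and were fixed as follows:

* the violating sample *seeds* the new series rather than being dropped
  (`restart_seeds_series = TRUE`, configurable). A slip usually ends at a
  new stable probe position; starting the new series there means a single
  slip costs one restart, not two.
* the first sample of a series has no predecessor and can never trigger a
  restart.

The step test uses the 3D Euclidean distance between consecutive raw
points, the same distance notion the navigation display uses. Acquisition
operates on tip points already expressed in the reference frame, so head
motion during the 1.5 s capture is tolerated by construction.

## Registration and error metrics

Paired-point registration uses Horn's closed-form absolute-orientation
solution: with centered moving and fixed point sets, the optimal rotation
is the unit quaternion maximizing `q' N q`, where `N` is the 4x4 symmetric
matrix assembled from the cross-covariance; the answer is the eigenvector
of the largest eigenvalue. Two properties motivated the quaternion route
over unconstrained least squares:

* a quaternion always encodes a proper rotation, so `det(R) = +1` holds by
  construction even for noisy, near-planar fiducial configurations where an
  SVD solution must be explicitly reflection-corrected;
* the solution is exactly the global least-squares optimum, which the test
  suite confirms against an independent SVD/Kabsch implementation (residual
  sum of squares equal within 1e-9 on 1,000 random instances).

A tie in the top eigenvalue (degenerate symmetric configurations) leaves
the optimal rotation non-unique; the implementation then picks the first
eigenvector, canonicalizes `w >= 0`, and emits a warning.

**FRE** is reported as the root-mean-square of the per-fiducial residuals,
the standard definition in the registration literature. Published tables of
this kind rarely state whether RMS or mean residual was used and physical
data cannot disambiguate the choice, so a mean-absolute variant is exposed
via `compute_fre(type = "mean")` for sensitivity checks.

**TRE** is evaluated at clinically relevant targets — the planned condyle
and the graft's center of gravity. In simulation the truth transform is
known and TRE is the displacement of the target under
`estimated` versus `truth`; in physical replay a probe-measured target
point stands in for the truth. Both contracts exist because intraoperative
TRE measurement necessarily uses the second form while every simulation
check uses the first.

`predict_tre_squared()` implements the standard first-order prediction for
isotropic fiducial localization error (FLE),

```
E[TRE^2(r)] = FLE^2 / N * (1 + (1/3) * sum_k d_k^2 / f_k^2),
```

with `d_k` the target's distance from the k-th principal axis of the
fiducial set and `f_k` the RMS fiducial distance from that axis. At 10,000
Monte-Carlo repetitions the empirical mean TRE^2 agrees with the prediction
to a few percent (the formula is first-order in FLE, so a few percent is
the expected agreement, and the acceptance suite allows 10%).

`registration_session()` mirrors the intraoperative workflow: acquire,
register, inspect FRE/TREs, repeat if unacceptable. No default error
thresholds are baked in — clinical acceptance levels for these errors are
not standardized and depend on the case — so the caller must supply an
acceptance policy (a threshold list or a predicate).

## Navigation and color coding

Tracked and planned bone segments are the *same* virtual point cloud, so
correspondence is by index and no nearest-neighbor search is performed.
This matters: nearest-neighbor matching would report near-zero distance
for a rotated-in-place segment, masking exactly the error the surgeon needs
to see. Per-point deviations are plain Euclidean distances
`d_k = ||q_k - p_k||`, and the per-tick summary (min/max/mean, fraction of
points under the lower scale endpoint) is what a renderer or logger
consumes; actual 3D rendering is out of scope.

The color scale is normative only at its endpoints: deviations under
1.0 mm map to dark green (`#006400`), above 4.0 mm to dark red
(`#8B0000`). Between the endpoints the default is linear RGB interpolation
between those two colors — chosen so that the midpoint deviation (2.5 mm)
maps to the exact RGB midpoint, giving a simple, monotone, testable
contract — and a 1.0 mm-binned stepped mode is provided for displays that
prefer discrete bands. Any endpoint colors can be configured; monotonicity
in the deviation holds in both modes.

Scene snapshots serialize clouds, transforms and distance maps to JSON
with 17 significant digits, which round-trips IEEE doubles exactly:
re-evaluating a loaded snapshot reproduces the stored distance maps bit
for bit.

## The synthetic phantom

The simulator is the stand-in for physical model surgery and supplies
ground truth for every upstream operation. Geometry is parametric, not
anatomical: the graft is 2–4 box prisms (6 mm half-width, the scale of a
fibular cross-section) laid along a mandible-like arc from the condyle
down the ramus and along the body to the junction with the residual
mandible. Anatomical realism is irrelevant to the math being tested;
users with real plans can load STL/PLY surfaces instead. The clinically
relevant targets are placed at the arc's free end (CON), the ramus-body
corner (ANG), the graft-mandible junction (JUN), plus the cloud centroid
(CENTER).

Default study conditions: 60-sample/40 Hz/0.5 mm acquisition, 25 Hz
navigation rate, 5 registration fiducials per object, and a fiducial
localization noise of 0.3 mm per axis — the order of magnitude of EMT
positional accuracy; vendor noise specifications are not published for
this stack, so the default is stated, not calibrated. Cloud sizes default
to 1,200 (mandible) and 900 (graft) points, dense enough that centroid and
distance-map statistics are stable while keeping every test and the
acceptance run within seconds. A single master seed with named substreams
per sensor/landmark makes every case byte-reproducible.

What the simulator does *not* model — and hence what passing tests do not
show about real data: metallic distortion and field inhomogeneity of the
EM volume, sensor mounting compliance, probe-tip calibration error, CBCT
segmentation error, and the shape mismatch of a physically assembled graft
beyond a single rigid offset (`graft_shape_error_mm` applies one small
rigid perturbation, a deliberate simplification of plate-fixation
distortion). The packaged per-case tables exist precisely because the
physical accuracies cannot be regenerated at desk scale.

`simulate_placement()` applies a known rigid placement error (bounded at
20 mm / 15 degrees, the small-motion envelope of a fixation correction) and
returns the closed-form displacement of each target. For a pure rotation
about the junction, displacement grows with distance from the rotation
axis (`2 r sin(theta/2)`), so CON moves most — the lever-arm effect that
makes a free-standing condyle the most misplacement-prone point.

## Postoperative accuracy statistics

The analysis module regenerates, from packaged per-case measurements of an
11-case phantom study, the summary and agreement statistics a
navigation-versus-CBCT evaluation reports:

* `summarize_mean_sd()`: mean and sample (n-1) SD, rounded
  half-away-from-zero to table precision (2 decimals for per-case values,
  1 for limits of agreement, 2 for correlation coefficients);
* `pearson_r()`, `linear_fit()`: correlation and OLS regression between
  navigation and CBCT displacement series;
* `bland_altman()`: differences taken as navigation minus CBCT with limits
  of agreement `mean +/- 1.96 SD`. Sign convention and multiplier are the
  ones that reproduce the published CON and ANG limits from the per-case
  values; both are configurable.
* `ks_normality()`: one-sample Kolmogorov-Smirnov against a normal with
  sample-estimated mean/SD. Estimating parameters from the same sample
  makes the plain KS p-value conservative; whether the original analysis
  applied a Lilliefors correction is unknowable from the printed results,
  so `lilliefors = TRUE` (via nortest) is offered as an option.

`reproduce_tables()` recomputes every packaged summary cell and compares
at printed precision, allowing one unit in the last printed digit. Three
cells need that single-unit slack rather than matching exactly, consistent
with the source having summarized unrounded internal values: the
navigation JUN SD (prints 1.41, per-case values give 1.40), the JUN
Pearson r (prints 0.44, computes 0.43) and the JUN upper limit of
agreement (prints 3.5, computes 3.4). All other cells — including every
headline accuracy figure — reproduce exactly; the acceptance suite pins
the exact ones and documents these three.

## Numerical choices and degenerate inputs

* Quaternion/matrix conversions use Shepperd's branch selection; unit norm
  is enforced to 1e-9 on construction.
* Collinear (or < 3) fiducials make registration underdetermined and raise
  a classed error; collinearity is detected via the second singular value
  of the centered moving set (threshold `1e-9` relative).
* Zero-variance inputs to correlation/regression raise errors rather than
  returning NaN; `bland_altman(x, x)` is well-defined (zero mean,
  zero-width limits) with the normality test skipped.
* Table rounding is half-away-from-zero with a 1e-9 guard against the
  binary representation of decimal ties.
* All coordinates are millimetres end to end; readers reject files without
  the `_mm` column suffixes rather than guessing units.

## Problem sizes

The default test and acceptance runs use 11-case fixture statistics
(deterministic), 1,000-instance registration property sweeps, 10,000
Monte-Carlo repetitions for the TRE prediction, and phantom clouds of
~1,000 points; the full suite completes in well under a minute on one
core. These sizes were chosen so that Monte-Carlo error is comfortably
below the tolerances being asserted.

## Known limitations

* Surface-based or ICP registration is out of scope; registration is
  paired-point only.
* The EM field is ideal: no distortion, jitter is white Gaussian, and
  sensors never drop out except via the explicit staleness timeout.
* The CLI's `navigate` stage replays recorded or simulated streams; there
  is no hardware interface.
* Rendering (projections, semitransparency, audio feedback) is left to a
  consumer of the per-tick colored point lists and summaries.
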