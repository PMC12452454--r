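---
title: "Estimating the knee adduction moment from two IMUs: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the knee adduction moment from two IMUs: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imukam)
```

## The estimation model

The external knee adduction moment (KAM) is the frontal-plane external
moment about the knee during stance and is widely used as a surrogate for
medial tibiofemoral compartment load. Gold-standard KAM requires optical
motion capture plus force plates. `imukam` implements a deliberately
minimal alternative that uses two inertial measurement units (IMUs):

* a **lower-back (L3) sensor**, whose globally vertical specific force
  `a_vert(t)` (in g, gravity-inclusive) is scaled by body weight to give a
  vertical ground reaction force surrogate,
  `GRF_VT(t) = BW * a_vert(t)` with `BW = m * 9.80665` N;
* a **lower-lateral-shank (LLS) sensor**, whose frontal-plane tilt gives
  the shank tilt angle `FP_STA(t)` after an additive offset anchors the
  quiet-standing value to an externally supplied initial angle.

The moment arm of the vertical GRF about the knee in the frontal plane is
approximated from shank geometry,

```
lever(t) = L_shank * sin(FP_STA(t))
KAM(t)   = GRF_VT(t) * lever(t)
```

and the product is evaluated sample by sample on the 200 Hz IMU timeline.
The model intentionally omits the center-of-pressure excursion and the
foot progression angle; both mainly shape the second (late-stance) KAM
peak, which is why the method is scored separately over the early and
late halves of single-limb support (SLS) and is expected to work best in
the early half.

Key assumptions: the trunk sensor's vertical acceleration reflects the
support limb's vertical GRF (strictly true only during single support,
which is exactly the analyzed window); the shank behaves as a rigid
segment between calibration and the analyzed step; and sensor axes are
mounted approximately aligned with the body planes, with residual
misalignment absorbed by the quiet-standing calibration and the FP-STA
offset.

## Orientation estimation

Initial orientation comes from a quiet-standing window (at least 0.5 s):
the mean accelerometer vector is taken as the gravity direction, the
minimal rotation mapping it onto the global vertical is composed with the
nominal mounting map, and the unobservable heading is fixed to the
nominal mounting heading. Windows whose mean acceleration magnitude falls
outside [0.9, 1.1] g are rejected as non-static.

From there the orientation is propagated by integrating the body-frame
gyroscope with one quaternion exponential update per sample and per-step
renormalization. The per-step rotation increment uses a cubic (4-point)
quadrature of the sampled rates — the integral over one step of the cubic
through samples `k-1..k+2`, with a trapezoid fallback at the sequence
ends. A plain rectangle or trapezoid rule leaves a phase-lag error of a
few hundredths of a degree at 200 Hz for gait-speed tilt excursions,
which is the same order as the noise-free recovery tolerance we test
against; the cubic quadrature removes it at negligible cost while still
being a strictly causal-window, one-update-per-sample scheme. Coning
corrections are not applied: the analyzed motions are dominated by a
single frontal-plane axis, and the round-trip test (simulator orientation
differentiated to gyro and re-integrated) bounds the residual at under
0.1 degrees over a trial.

No accelerometer, magnetometer or bias correction is applied during
movement. A gyroscope bias `b` therefore drifts the tilt linearly (at
most `b*t` degrees after `t` seconds, tested at `b = 0.5` deg/s). Over a
single-limb-support window (under 0.5 s) this is well below the
waveform-level effects of interest.

Tilt sign convention: frontal tilt is positive when gravity tips toward
the sensor's positive frontal axis, i.e. the sign a static accelerometer
reading `asin(a_frontal)` reports. The adduction-positive direction is a
configuration flag (`adduction_sign`), defaulting to the right-limb
convention.

## Filtering

All streams are low-pass filtered with a 4th-order Butterworth applied
forward and backward (zero phase). Cutoffs follow the conventions for
this sensor configuration: 10 Hz for the vertical acceleration (most GRF
signal content lies below 10 Hz), 12 Hz for angular velocity, 10 Hz for
force-plate GRF. The filter order is a package choice — 4th order is the
biomechanics community default. Because the filter is applied twice, the
amplitude response at the cutoff is -6 dB (factor 0.5), not the
single-pass -3 dB; tests assert this consequence explicitly.

Edge handling uses odd-reflection padding of three filter orders per end
plus constant steady-state initial conditions, so constants pass through
bit-exactly and edge transients decay inside the padding rather than
inside the analyzed window. The analyzed SLS window always sits well
inside a longer recording, which is why a short padding suffices.
Filtering is applied to the globally resolved vertical acceleration
(after rotation, before body-weight scaling); cutoffs can be set to
`NULL` to bypass filtering entirely in noise-free validation runs.

## Event detection and normalization

Single-limb support is detected from the contralateral force plate: the
first maximal run of samples strictly below 10 N, ending on the last
sample before the force returns to or above 10 N. Boundary semantics are
deliberately strict — `< 10` enters the window, `>= 10` leaves it, with
no hysteresis — so a sample at exactly 10 N never counts as unloaded. A
run touching either end of the recording is reported as a "truncated SLS"
error rather than silently accepted, because the corresponding support
window cannot be certified complete. The detector also returns all
below-threshold runs for diagnostics, while analysis uses one SLS per
trial.

The detected window is time-normalized to 101 points (0–100 % in 1 %
steps, the gait-analysis convention) by linear interpolation; because
normalization is time-based it is independent of the source sampling
rate, letting 200 Hz estimates and 100 Hz force-plate series share one
grid. The early/late split defaults to 0.5 of the normalized window —
the published description of the split we follow does not restate its
exact boundary, so the half-way point is used and exposed as
`split_fraction` for other conventions. The boundary grid point belongs
to both segments, so each default segment has 51 points.

## Waveform similarity (CMC)

Similarity between an estimated and a reference waveform is scored with
the coefficient of multiple correlation in its within-day, two-waveform
form: with `Y_ft` the value of waveform `f` at frame `t`,

```
CMC = sqrt(1 - [ S_ff' within-frame MS over T(F-1) ]
             / [ total MS over (FT-1) ])
```

Among the published CMC variants (within-day, between-day,
inter-protocol) this is the only one applicable to a single trial's
estimate-versus-reference pair, and it reproduces the characteristic
failure mode: when two waveforms differ mainly by a vertical offset, the
within-frame mean square exceeds the total mean square, the radicand goes
negative, and the CMC is complex. Such results are reported as `NaN` —
never clipped to zero — and kept as their own category, because an offset
failure and a genuinely dissimilar shape are different findings.
Similarity bands are half-open with ties to the upper band: none
[0, 0.65), moderate [0.65, 0.75), good [0.75, 0.85), very good
[0.85, 0.95), excellent [0.95, 1].

## The synthetic gait model

Because the reference (optical) KAM computation is out of scope, the
package validates its estimation chain against a forward simulator whose
ground truth is known exactly. A trial consists of a quiet-standing
prefix (default 2 s, both feet each carrying half body weight), a 0.3 s
cosine blend, and steady-state periodic gait at the configured cadence
(defaults 115/100/85 steps/min emulate the preferred/reduced/lowest
study conditions) with a 60 % stance and 10 % double-support gait model.

Per-foot vertical GRF is a smooth windowed shape in body-weight units:
the bimodal default has peaks of 1.10 BW near 25 % and 75 % of stance
with a 0.76 BW midstance valley, and the unimodal option (emulating the
flattened GRF seen at very low step rates) a single 1.10 BW peak. The
parameterization is a smoothness choice, not a claim about any specific
subject's waveforms; its average vertical support over full cycles comes
out within 10 % of body weight, which is the physical walking-support
condition the tests assert. Frontal shank tilt is a baseline
(`initial_sta`, default 3 deg) plus a raised-cosine bump per stance
(amplitude default 4 deg), giving KAM peaks around 0.4 N·m/kg —
mid-range for healthy adult walking.

The forward model is constructed to be the exact inverse of the
estimator's assumptions: the trunk vertical specific force is defined as
total vertical GRF over body weight (equal to the stance-limb GRF
throughout single support), the shank rotates about the global
anteroposterior axis, the gyroscope is the analytic derivative of that
orientation, and the accelerometers read the rotated gravity direction
plus the derived vertical acceleration. Ground-truth KAM satisfies
`kam = grf * L_shank * sin(sta)` identically, and an accessor returns it
directly so validation never recomputes truth through the estimator
under test. Independent Gaussian noise (defaults 0.05 g accelerometer,
1 deg/s gyroscope) is added to every channel; all randomness flows from
one integer seed and trials are bit-reproducible.

What the simulator does **not** emulate — and what passing tests
therefore do not show about real data: trunk anteroposterior/mediolateral
accelerations and pelvis rotations, soft-tissue artifact, the real
(imperfect) correspondence between trunk acceleration and stance-limb
GRF during double support, shank swing-phase kinematics, foot-progression
and center-of-pressure effects, and any systematic accelerometer scale or
gyroscope bias error. The simulator validates the *estimation chain*
(calibration, integration, filtering, event detection, product, scoring),
not the physiological adequacy of the two-parameter KAM model itself;
the latter is what the shipped per-trial reference CMC table summarizes.

## Numerical choices and degenerate inputs

* `g = 9.80665` m/s² fixed; angles stored in degrees, quaternion math in
  radians internally; quaternions renormalized every step and checked to
  unit norm within 1e-9.
* Negative GRF-VT values are not clamped: walking has no flight phase,
  so a negative excursion flags an estimator fault that clamping would
  hide.
* The FP-STA anchor uses the mean frontal tilt over the calibration
  window rather than a single sample, for noise robustness.
* A series too short for filter padding, a cutoff at or above Nyquist, a
  calibration window under 0.5 s or with non-1-g mean, non-finite gyro
  samples (reported with their index), mismatched series lengths, and
  time columns deviating from uniformity by more than 1 ppm all raise
  immediate, named errors rather than propagating silently.
* Pipeline errors are prefixed with the failing stage name
  (`read`, `filter`, `calibration`, `propagation`, ...).
* CSV round trips write 17 significant digits so re-reading is
  bit-identical.

## Problem sizes used in validation

Simulated trials use 4 strides (~6.3 s at 200 Hz, ~1270 samples) — enough
for a steady-state mid-trial support window with margins on both sides —
and the Monte-Carlo recovery check uses 20 seeded trials at the default
noise levels, the trial count at which the pass criterion (early-SLS CMC
at least 0.95 in at least 15 of 20) is stable across seed sets. These
sizes are the package's own validation choices.

## Known limitations

The estimator inherits the two-parameter model's blind spots: late-SLS
accuracy is structurally limited without COP and foot-progression
information, and very low cadences that flatten the GRF to a unimodal
shape degrade waveform similarity — both effects visible in the shipped
reference table. Orientation drift is unconstrained during movement, so
the method should not be extended to windows much longer than a stance
phase without adding a complementary attitude correction. The CLI and
file formats are CSV-only by design; vendor formats should be converted
upstream.
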