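---
title: "Risk-adaptive fall detection from skeleton streams: models and methods"
author: "fallsentry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Risk-adaptive fall detection from skeleton streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fallsentry)
```

## The problem

Unintentional falls are a leading cause of injury-related death among the
elderly, and a fall that goes unnoticed is far more dangerous than the fall
itself.  Depth sensors that report a tracked human skeleton — twenty named
joints with metric 3-D coordinates at 30 frames/s, plus a floor-clipping
plane — make unobtrusive in-home fall monitoring possible without wearables
or cameras that record identifiable images.

fallsentry implements a *risk-adaptive* detector: before deciding how
aggressively to monitor, it estimates the subject's **fall-risk level** from
gait abnormality measures, and subjects whose gait suggests physical
weakness are watched with more sensitive thresholds.  Detection itself is
two-stage: a cheap per-frame stage raises *potential fall* candidates; a
confirmation stage examines the height pattern that follows and either
confirms or rejects each candidate.

## Per-frame kinematics

All quantities derive from the joint coordinates $(x, y, z)$ (meters;
x right, y up, z away from the sensor) and the floor plane
$(A, B, C, D)$, where $D$ is the camera height above the floor.

**Height above the floor.**  The height of a joint is its point-to-plane
distance

$$H = \frac{|Ax + By + Cz + D|}{\sqrt{A^2 + B^2 + C^2}},$$

which is invariant to any positive rescaling of the plane vector.  A
degenerate plane ($A = B = C = 0$) is an error; an untracked joint yields an
unavailable (`NA`) height that downstream stages treat as a skipped frame.

**Speed.**  Instantaneous speed is $|d_c - d_p| / (t_c - t_p)$.  Joint
positions are compared two frames apart (skip-one sampling), so the
denominator is $1/15$ s at 30 frames/s; the skip count is configurable.
The stream-level speed channel uses the full 3-D displacement of the head,
so both a horizontal running burst and a vertical drop register.  Speeds are
passed through a short running median (3 samples by default) because a
0.01 m per-coordinate sensor jitter alone produces spurious
fractions of a m/s at this sampling rate.

**Direction.**  A displacement below the stationarity epsilon (0.01 m per
sample) is `stationary`.  Otherwise, if the dominant axis carries at least
the dominance fraction (default 0.8) of the Euclidean displacement the
motion is axis-aligned (`axis_x`/`axis_y`/`axis_z`); ties at the boundary
classify as axis-aligned; anything else is `irregular`.  For irregular
motion the distance travelled is the in-plane Euclidean length
$\sqrt{(x - x')^2 + (y - y')^2}$ — an axis-projected difference would
underestimate it.  Including the depth axis is available behind a
configuration flag and off by default.

**Acceleration.**  No closed form is prescribed for acceleration, but the
normal-path detector needs one; it is defined as the first difference of the
(smoothed) speed over the sample interval, followed by a 3-sample running
median.  Both widths are configuration keys.

## Gait-derived fall-risk factors

Three factors compare a previous frame (PF) and current frame (CF), on axes
chosen relative to the walking direction (lateral measures use x when
walking along z and vice versa):

* **Step symmetry** — the change in the feet's separation on the movement
  axis, $(\mathrm{sep})_{PF} - (\mathrm{sep})_{CF}$ with
  $\mathrm{sep} = |R_{foot} - L_{foot}|$.  Sampled at successive *step
  extremes* of the signed separation signal, where the separation equals a
  step length, this is exactly the left/right step-length inequality of a
  limping gait.
* **Trunk sway** — the torso's lateral offset from the hip midpoint,
  averaged over the two frames; a proxy for balance difficulty.
* **Arm spread** — the change in mean torso-to-arm lateral *distance*
  (hands stand in for the arms as the distal proxy, via a configurable
  joint-alias table); positive values mean the arms are opening, a
  balance-recovery gesture.

Aggregated over a 2 s window (mean of absolute values by default), the
subject is flagged **high risk** when *any* aggregate exceeds its threshold
(defaults: 0.10 m, 0.05 m, 0.15 m).  The OR rule is deliberate: any gait
abnormality triggers intensive monitoring.  The thresholds are calibration
choices — the contribution is the adaptive structure, not a particular
cut-off — and all are configuration keys.

Two estimator details matter in practice.  The movement axis is carried
forward through stationary or irregular frames and only *switches* after
five consecutive frames classified on the other axis, so a single
jitter-driven classification cannot flip it.  And step-symmetry samples are
only taken while the subject is actually stepping (the tracking joint must
have translated at least 0.06 m over the surrounding 1/3 s on the carried
axis); without this, sit-down and lie-down transitions masquerade as large
step asymmetries.

## The two-stage, five-process detector

Per frame:

1. **P1 — subject detection.**  The key joints (head, shoulder center, hip
   center) must be tracked.
2. **P2 — initial assessment.**  Kinematics and risk factors are computed
   and buffered (3 s).  A skip-one head speed above `velocity_high`
   (2.0 m/s) raises a potential fall immediately and hands over to P5.
   Otherwise the current risk level selects the path.
3. **P3 — high-risk path.**  Intensive monitoring: the *every-frame* speed
   against a lowered threshold (0.75 × 2.0 = 1.5 m/s) and the head height
   against a raised near-floor threshold (1.25 × 0.5 = 0.625 m).
4. **P4 — normal path.**  Head below the near-floor height (0.5 m) or
   acceleration above 10 m/s².
5. **P5 — confirmation.**  Within 1.5 s after the candidate the head must
   end below the near-floor height with no recovery above 0.8 m, the window
   must show a sustained net drop of at least 0.15 m, the pattern must not
   be a small up/down oscillation (two or more height-derivative sign
   changes with amplitude under 0.15 m — the signature of walking and
   running), and the hip must corroborate by also ending below the recovery
   height.  Failing candidates are rejected with the discriminating
   evidence attached.

**Intentional descents.**  Sitting down on the floor or lying down reaches
the near-floor zone without being a fall.  A descent is recognized as
intentional when, over the last 2 s, the (trailing-mean) head height was
monotone non-increasing (rises above the running minimum of at most 0.04 m
tolerated, so jitter does not break the run but walking's height bob does)
*and* the descent rate — measured over a 1/3 s lag, because at shorter lags
jitter noise exceeds the decision margin — stayed below 1.0 m/s.  Both
stage-1 paths consult this recognizer before raising a candidate: a
recognized slow descent vetoes the alert and latches until the head
recovers above 0.8 m, so resting on the floor afterwards stays silent.
High-velocity P2 alerts are never vetoed.  The rate bound is what keeps a
fall from a chair — preceded by motionless sitting, which a monotonicity
test alone would walk straight through — out of the intentional class.

**Candidate lifecycle.**  One candidate is open at a time; a new velocity
spike during an open confirmation window extends the window; a confirmed
fall suppresses further detection until the head recovers above the
recovery height; a rejection is followed by a 0.5 s refractory.  Given the
same stream and configuration the event log is byte-identical —
determinism is part of the contract and tested as such.

## The motion simulator

Every stage is testable without sensor hardware through a seeded
channel-based simulator: each activity segment drives scalar channels (head
height, lateral lean, signed foot separation, arm spread, body position)
from which the 20-joint skeleton is synthesized, with Gaussian jitter
(0.01 m per coordinate) added.  The repertoire covers standing, walking and
running (sinusoidal head bob ≤ 0.06 m), sitting on a chair or on the floor,
lying on the floor (raised-cosine descent, 3.7–4.2 s — the pace at which
people actually lie down), picking an object, and three fall types whose
drop phase is an accelerating quadratic so that impact speeds exceed
2 m/s, with total durations of 1.3–1.9 s to rest.  Gait presets: `normal`,
`slow`, and `weak` (0.2 m step-length asymmetry, 0.1 m sway).  Walking
enters its gait cycle at the phase matching the current foot separation so
segment boundaries do not fake a step-length change.

The simulator is stylized, not biomechanical: joints move on
piecewise-smooth trajectories, limbs do not articulate, occlusion and
tracking dropouts are absent unless injected, and the jitter is white
rather than temporally correlated.  Passing tests therefore demonstrate
that the pipeline recovers the *structure* it assumes (drop speeds, descent
durations, gait asymmetry) — not performance on real sensor recordings.

`standard_suite()` mirrors a 30-fall / 40-ADL benchmark composition with
randomized parameters.  ADL sequences use the normal/slow presets (such
benchmarks' activities are performed by healthy adults); weak gait appears
in fall sequences and in the dedicated risk tests.  A consequence of the
sensitive P3 path is worth stating plainly: a *high-risk* subject lying
down slowly can trip the raised near-floor threshold if the descent
recognizer fails, so the false-alarm behaviour for weak-gait subjects
depends on that recognizer more than it does for others.

## Accelerometer replay

For benchmarks that ship only accelerometer magnitudes, the adapter
reconstructs a head-height series from an initial height plus the
acceleration record.  Two modes are provided: cumulative subtraction of the
deviation from gravity, $h_i = h_{i-1} - |a_i - g|\,\Delta t$ (default),
and single integration of $(a - g)$ into a vertical velocity.  Both are
documented as benchmark-emulation heuristics, not physical models: units
must be declared explicitly (`ms2` or `g`), heights are clipped at zero,
and the first element equals the supplied initial height.

## Numerical choices and degenerate inputs

* Skip-one sampling (1/15 s) for speed; every-frame speed only on the
  sensitive path, with a wider (5-sample) median because its noise floor is
  higher.
* Direction dominance ties (ratio exactly at 0.8) classify as
  axis-aligned.
* Missing or untracked joints yield `NA` quantities; frames whose key
  joints are untracked are skipped, never fatal.
* Frame spacing deviating from the nominal rate by more than 20% is flagged
  as a gap on the stream.
* CSV round-trips are exact to 6 decimal places (the declared precision).
* Windows shorter than the risk window return an *insufficient* assessment
  that falls back to the low-risk path with a caveat rather than guessing.

## Problem sizes used in the tests

The bundled tests run the full 70-sequence suite once (about a second),
100 + 100 seeded walking streams for risk recovery, 1000-case oracle
comparisons for the geometric kernels, and 20-stream round-trip checks.
These sizes keep the default check fast while leaving every code path
exercised.

## Known limitations

* Single subject; no multi-person tracking or identity management.
* The detector replays streams (files or simulator); there is no live
  sensor capture loop, and no alarm delivery.
* Risk thresholds are calibrated on the simulator's presets; real
  deployments should recalibrate `risk$threshold` on reference recordings.
* The accelerometer adapter is a replay heuristic; it cannot recover true
  heights from acceleration alone.
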