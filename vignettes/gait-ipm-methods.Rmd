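---
title: "Shank-IMU stride reconstruction with an inverted-pendulum velocity update: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shank-IMU stride reconstruction with an inverted-pendulum velocity update: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitipm)
```

## The estimation problem

A six-axis IMU strapped to the shank just above the malleolus measures
specific force $a^S(k)$ and angular velocity $\omega^S(k)$ in its own
moving frame. Stride length, stride velocity and shank vertical
displacement require the sensor trajectory in a laboratory frame, i.e. a
double integration of gravity-free acceleration — which diverges within
seconds under sensor bias and orientation error unless the integral is
re-anchored once per gait cycle. `gaitipm` implements the re-anchoring
strategy in which the anchor is not "zero velocity" (ZUPT) but the
tangential velocity of an inverted pendulum pivoting about the stationary
malleolus at mid-stance.

Frames and conventions:

* Lab frame $E$: $x$ vertical (superior), $y$ horizontal, $z$ lateral;
  the gravity direction is $g^E = (1,0,0)^T$ and wherever a gravity
  *vector* is needed it is $9.80665 \cdot g^E\,\mathrm{m/s^2}$.
* Sensor frame $S$: $x$ along the shank toward the knee, $y$
  posterior/anterior, $z$ medial/lateral.
* Quaternions are $[w, x, y, z]$, Hamilton product, canonicalised to
  $w \ge 0$ in constructors; $q^{SE}$ rotates sensor vectors into the lab.

## Pipeline

**1. Events** (`detect_gait_events`). The sagittal tilt
$\theta_z = \int \omega_z\,dt$ (linearly detrended — a gyro bias of
$b$ rad/s tilts the whole integral by $bt$ and would otherwise swamp the
extrema) provides shank-max-forward (SMF, tilt maxima) and
shank-max-backward (SMB, tilt minima). Heel strike is the first
prominent peak of $\omega_z$ after an SMF; toe off is the minimum of
$\omega_z$ between a heel strike and the following SMB; mid-stance (MS)
is the maximum of $\omega_z$ strictly between heel strike and toe off.
Strides are the half-open intervals between successive mid-stances.

**2. Orientation** (`quat_from_gravity`, `propagate_orientation`). At
every mid-stance the accelerometer is assumed to read pure gravity, and
the orientation is re-initialised with the shortest-arc quaternion
mapping the normalized reading onto $g^E$: half-angle terms
$\cos\frac\theta2 = \sqrt{\tfrac12(1+\hat a \cdot g^E)}$,
$\sin\frac\theta2 = \sqrt{\tfrac12(1-\hat a \cdot g^E)}$, axis
$\hat a \times g^E$ **normalized** (as printed, the raw cross product has
norm $\sin\theta$ and would give a non-unit quaternion; the explicit
renormalization in the propagation formula shows unit quaternions are
intended). The antipodal case ($\hat a \approx -g^E$, sensor upside
down) has an undefined axis and falls back to a 180° rotation about the
fixed axis $(0,1,0)$. Within each segment the orientation is propagated
one sample at a time,
$q(k) = \mathrm{normalize}\!\big(q(k-1) + \tfrac12 q(k-1)\otimes[0,
\omega^S(k)]\,\Delta t\big)$ — deliberately the plain first-order scheme,
with no smoothing or sensor-fusion filter.

**3. Velocity and drift removal** (`integrate_velocity`,
`ipm_update_velocity`, `remove_drift`). Lab-frame linear acceleration
$\tilde a^E = q a^S q^* - 9.80665\,g^E$ is integrated trapezoidally. At
each mid-stance the update velocity is
$\breve v^E = \omega^E \times r^E$ with
$\omega^E = q\,\omega^S q^*$ and $r^E = r \cdot q\,\hat a^S q^*$ — the
lever arm from the malleolus to the sensor along the accelerometer
direction, rotated into the lab frame (a cross product is only
meaningful with both factors in one frame; by the gravity alignment
$r^E = r\,g^E$ exactly). Each segment's velocity starts at
$\breve v(ms_i)$; the residual drift is modelled as a straight line in
the sample index and fixed by the two endpoint mismatches, so the
corrected velocity equals the update velocities at both boundaries *by
construction* (to $10^{-12}$, tested). The baseline method substitutes
$\breve v \equiv 0$ (ZUPT).

**4. Trajectory and stride frame** (`integrate_position`,
`stride_frame_rotation`, `transform_stride`). Corrected velocity is
integrated to a lab trajectory; for each stride a frame $P$ is built
with $y$ along the normalized inter-mid-stance displacement,
$z = \mathrm{normalize}(g^E \times y)$, $x = y \times z$. The basis is
orthonormal by construction, so the rotation is its transpose (a guard
asserts orthonormality first). The transform subtracts the stride's
starting position — the printed transform has no origin shift, but all
reported parameters are differences, so the choice is observationally
equivalent and makes per-stride trajectories directly comparable.

**5. Parameters** (`stride_length`, `shank_vertical_displacement`,
`stride_timing`). Stride length is the forward ($y_P$) displacement
between bounding mid-stances; vertical displacement the maximum $x_P$
excursion above the stride's starting height (the mid-stance height is
the natural baseline because mid-stance is the segmentation reference);
duration the interval between the stride's heel strike and the next
one, velocity the ratio. Length uses mid-stance boundaries while
duration uses heel strikes — implemented literally; the heel strike
paired with stride $i$ is the one inside $[ms_i, ms_{i+1})$, and the
final stride's closing heel strike is the first one detected after the
last mid-stance (`NA` duration if the recording ends before it).

## Why `flip_z`, and the yaw question

Gravity alignment cannot observe heading: any rotation about $g^E$ is
invisible to the accelerometer. The stride frame $P$ makes the final
parameters heading-invariant, but *intermediate* lab-frame quantities are
only comparable with an external reference if the hidden yaw is zero.
With the sensor $z$ axis chosen along the lab $z$ axis (one of the two
anatomical mountings), the sensor-to-lab rotation is a pure rotation
about $z$ and the shortest-arc construction recovers it *exactly* — no
yaw offset. The simulator uses this mounting so that estimated linear
acceleration and velocities can be compared sample-by-sample with ground
truth. The price is polarity: with this mounting the printed detection
rules apply to $-\omega_z$, so `flip_z = TRUE` is the package default;
the mirror mounting (other shank, or sensor flipped) uses
`flip_z = FALSE`. This is exactly the left/right switch a practitioner
needs anyway, and it is exposed on the CLI as `--flip-z`.

## The simulator: a stated world

`simulate_walk` generates planar sagittal gait in which the method's
assumptions hold by construction, with analytic ground truth:

* The sagittal rate profile (in the detection convention) is a C1
  piecewise-cosine curve through one set of nodes per cycle — mid-stance
  ($-0.3A$, the unique signed maximum of its stance), toe off ($-2.8A$,
  the stance minimum), a swing peak (solved per cycle so each cycle's
  tilt integral is zero, i.e. the tilt is periodic), a post-SMF minimum
  ($-1.2A$), heel strike ($-0.4A$, the first peak after SMF) and a
  post-heel-strike dip ($-1.5A$). Every node has zero slope, so the
  constructed extrema are exactly the events the detector must find. The
  amplitude $A$ is set so the tilt spans ± `shank_tilt_amplitude_rad`.
* During stance the malleolus is fixed and the shank pivots about it —
  the pendulum assumption holds exactly; because mid-stance is a node
  (zero angular acceleration), the sensor's linear acceleration there is
  just the centripetal term $r\dot\psi^2 \approx 0.02\,\mathrm{m/s^2}$,
  so the accelerometer reads (almost pure) gravity as assumed.
* During swing the malleolus advances one stride length on a quintic
  smoothstep with a cubed-sine lift (`swing_lift_m`, default 0.08 m);
  both have vanishing first and second derivatives at the joins, so
  velocity *and* acceleration are continuous at every stance/swing
  boundary.
* A 1 s quiet-standing prefix precedes a pivoting lead-in (solved so the
  standing tilt is zero) whose SMF/HS signature lets the detector
  bracket the first mid-stance; a tail past the final heel strike gives
  the last stride a duration. Commanded strides = detected segments.
* `cycle_variability` (default 0.1) jitters the mid-stance rate
  multiplicatively per cycle, clipped so mid-stance remains the stance
  maximum. Healthy gait varies stride to stride by roughly this much,
  and without it the ZUPT error would be the same constant every stride,
  making the error-variability comparison between methods degenerate
  rather than merely easy. `ms_rate_scale = 0` replaces the mid-stance
  node by a short exactly-zero plateau: the shank is genuinely still,
  and the pendulum and zero-velocity updates must coincide bit-for-bit.
* Noise is i.i.d. Gaussian plus constant bias per channel, applied after
  ground truth is recorded; one seed drives a single RNG stream
  (variability draws first, then accelerometer, then gyro noise).

What the simulator does **not** emulate: out-of-plane motion, soft-tissue
artefacts, heel-strike impact transients, double support, pathological
(shuffling) gait, or magnetometer-relevant effects. A green test
establishes that the pipeline recovers the parameters of a world where
the model's assumptions hold (with realistic noise), not that it handles
abnormal gait.

## Numerical choices and honest limits

* **Tolerances.** Structural identities (endpoint anchoring of the drift
  model, rotation orthonormality, velocity x duration = length, gravity
  alignment post-condition) are tested at $10^{-9}$–$10^{-12}$: they hold
  by construction, so failures indicate bugs, not noise.
* **First-order propagation.** For constant rate about a fixed axis the
  scheme's leading error term cancels and convergence is effectively
  second order; with a varying axis it is first order. At 100 Hz and a
  realistic ~6 rad/s swing peak, the orientation error peaks around
  mid-swing and leaves an RMS linear-acceleration error of about
  0.13 m/s² (0.04 at 400 Hz, halving with $\Delta t$). This barely
  affects the stride parameters (length error ~0.4% at 100 Hz) because
  the per-stride linear drift model absorbs the integrated error — which
  is precisely the method's design.
* **Peak search.** Prominence-based, plateau-aware, with no external
  signal-processing dependency. Defaults: 0.2 rad/s prominence for rate
  peaks, 0.05 rad for tilt extrema, minimum separation of 0.25 median
  cycle applied to *tilt* extrema only — heel strike and the swing peak
  are ~0.2 cycles apart in any physiological shank signal, so a
  0.25-cycle separation on rate peaks would delete heel strikes; the
  HS-after-SMF / TO-before-SMB / MS-between windows already enforce
  per-cycle uniqueness for the rate events.
* **Degenerate inputs.** Antipodal gravity alignment falls back to a
  fixed axis; a stride displacement parallel to the vertical makes the
  stride frame undefined and is an error; cycles whose HS/TO ordering
  cannot be satisfied are dropped with a message; mid-stances whose
  accelerometer magnitude is >20% away from $g$ produce a warning but
  proceed.
* **Configuration formats.** JSON (via jsonlite) rather than YAML: no
  YAML parser is available in the target environment, and the config is
  a flat list either way.

## Defaults that matter

| parameter | default | why |
|---|---|---|
| `r_m` | 0.05 m | sensor strapped immediately above the malleolus |
| sampling | 100 Hz | typical clinical IMU rate |
| stride | 1.2 m / 1.1 s | normal adult self-selected walking |
| `stance_fraction` | 0.6 | canonical 60/40 stance/swing split |
| `shank_tilt_amplitude_rad` | 0.6 | ~±35° sagittal shank excursion |
| `cycle_variability` | 0.1 | healthy stride-to-stride variability |
| LOA multiplier | 1.96 | 95% limits of agreement |
| `prominence_rad_s` | 0.2 | above gyro noise, below any gait peak |
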