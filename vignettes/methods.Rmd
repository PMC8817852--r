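---
title: "Landmark-based learning-state assessment: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Landmark-based learning-state assessment: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(facevigil)
```

# The problem and the signal model

A webcam watching a person produces a video stream; a face-alignment
detector reduces each frame to 68 labelled 2D landmark points (jaw 0–16,
brows 17–26, nose 27–35, eyes 36–47, outer lips 48–59, inner lips 60–67, in
the 0-based numbering used by dlib-style detectors). `facevigil` operates
entirely downstream of that reduction: its input atom is a
`landmark_frame` — frame index, timestamp, face-presence flag, and the 68
points in pixel coordinates (origin top-left, y down). Working on landmarks
rather than pixels keeps every stage cheap, deterministic, and testable
offline.

Three per-frame features drive the assessment.

**Eye aspect ratio (EAR).** For the six points of one eye, ordered outer
corner, two upper-lid points, inner corner, two lower-lid points,

$$\mathrm{EAR} = \frac{\lVert P_2 - P_6\rVert + \lVert P_3 - P_5\rVert}
{2\,\lVert P_1 - P_4\rVert}.$$

The ratio is dimensionless and invariant under translation, rotation and
uniform scaling of the six points, so it is insensitive to where the face
sits in the image and how large it appears. The per-frame value is the
weighted mean of the two eyes; with no evidence for asymmetric weighting the
default weight is 0.5. A frame is *closed* ($E=0$) when the ratio falls
below `ear_threshold` (default 0.20, boundary inclusive on the open side).

**Mouth aspect ratio (MAR).** The analogous ratio is computed from
*inner-lip* landmarks: vertical pairs (61, 67) and (63, 65) over the
horizontal pair (60, 64), 0-based. Inner lips are the deliberate choice:
outer-lip ratios differ across people with different lip thickness even
with the mouth shut, while the inner-lip seam converges near zero for
everyone. The simulator's lip-thickness variants exercise exactly this
property (closed-mouth inner MAR stays below 0.05 while an outer-lip ratio
more than doubles). A frame is *open* ($M=1$) at `mar_threshold` (default
0.35) or above. Maximal open runs become episodes graded by duration
`COUNTER`: $Y=0$ for ordinary opening (speaking, eating), $Y=1$ for a yawn,
$Y=2$ for a deep yawn.

**Head pose.** Fourteen comparatively rigid landmarks (four brow corners,
four eye corners, the two nose-base corners, the two outer mouth corners,
the lower-lip centre, the chin tip) are matched to a rigid 3D face model.
With camera intrinsics $f_x, f_y, c_x, c_y$ and the world-to-camera
transform $X = RU + T$, projection normalises by depth, applies the
radial–tangential distortion polynomial, and maps to pixels. `solve_pose`
inverts this: a direct linear transform (DLT) on undistorted normalised
coordinates initialises $[R\,|\,T]$, and Levenberg-damped Gauss–Newton
iterations minimise the summed squared reprojection error
$J = \sum_i (\hat x_i - x_i)^2 + (\hat y_i - y_i)^2$. Euler angles follow
the convention $R = R_z(\mathrm{roll})\,R_y(\mathrm{yaw})\,
R_x(\mathrm{pitch})$ — pitch nods about x, yaw turns about y, roll sways
about z, reported in degrees.

# State machines and the fused rule

Per-frame codes feed three counters and a window aggregator:

- $E \in \{0,1\}$ per frame; blinks are maximal closed runs bracketed by
  open frames; the eye-closing rate (PERCLOS) is the closed fraction of a
  window's face-present frames.
- $M \in \{0,1\}$ per frame; episodes classified by duration with
  `yawn_frames` = 25 and `deep_yawn_frames` = 50 as run-length boundaries.
- Head normality $H = 1$ only when *all three* Euler channels lie within
  ±`euler_threshold_deg` (15°). Each channel keeps a consecutive
  out-of-range counter; a counter above `head_frame_threshold` (60) yields
  the head event $P$: 1 (fatigue) for pitch or roll, 2 (sight deviation)
  for yaw, with fatigue taking precedence when both hold.

The window rule (default window: 60 s at 25 fps = 1500 frames) raises an
alert when any of these clauses holds:

- eye-closing rate strictly greater than `closing_rate_threshold` (0.2);
- at least `yawn_alert_count` (2) yawns, or `deep_yawn_alert_count` (1)
  deep yawns;
- any channel's *total* out-of-range frames in the window exceed
  `window_head_frames` (120).

Each satisfied clause is reported as a reason (`CLOSING_RATE`, `YAWN`,
`DEEP_YAWN`, `HEAD_PITCH`, `HEAD_YAW`, `HEAD_ROLL`). A window without a
single face-present frame reports `NO_FACE` and never alerts: absence of
evidence is surfaced as lost coverage, not fatigue. `assess_window`
(aggregating frames) and `evaluate_record` (auditing tabulated aggregates)
share one rule implementation, and a test asserts they agree.

# Design choices where the design was open

Several points were genuinely underdetermined; the package resolves each
one explicitly and configurably.

**"Or" versus "and" in head normality.** Read literally, a rule declaring
the head normal when *any* channel is in range would almost always hold —
a head turned 90° still has pitch and roll near zero. The per-channel
counters make sense only if each channel signals abnormality on its own, so
normality requires all three channels in band. This is the one deliberate
reinterpretation in the package.

**Episode duration boundaries.** The class intervals for $Y$ overlap at 25
and 50 if read as closed ranges; the implementation uses $Y=0$ for
`COUNTER` ≤ 25, $Y=1$ for (25, 50], $Y=2$ for > 50, matching the
prose reading ("more than 25 but less than 50", "more than 50"). Both
boundaries are configuration keys.

**The right nose-base pose point.** The published 14-point list names
landmark 39 twice (once as a left-eye corner, once as "nose lower right").
A nose-base partner symmetric to 31 is geometrically required for a
well-conditioned correspondence set, so the package uses landmark 35, with
`nose_lower_right` exposed in the configuration for anyone who wants the
literal list.

**Euler convention and gimbal handling.** No decomposition order is
canonical; the package fixes $R_z R_y R_x$, which makes the axis
assignments of pitch/yaw/roll match their colloquial meanings, and
round-trip tests pin the convention down. In this order the middle (yaw)
angle is confined to [−90°, 90°]; at |yaw| = 90° the decomposition is
degenerate and roll is set to 0. Head-pose monitoring operates far from
that configuration.

**Deep yawns are not also yawns.** An episode crossing the deep-yawn
boundary counts once, in the deep-yawn column; the alert clauses treat the
two classes separately. Episodes spanning a window boundary keep their
global frame counter and are attributed to the window in which they end.

**Consecutive counters versus window totals.** The 60-frame event counters
are consecutive by definition (they reset the moment a channel re-enters
the band); the 120-frame alert clause counts a window's *total*
out-of-range frames per channel. Both quantities are computed and logged;
the windowed total is the alerting default. The two thresholds are
independent configuration keys, as their relation is not fixed by the
method.

**Counters across face loss.** When the face-presence flag drops, the head
counters reset: an unobserved head cannot extend a "consecutive" run.
Faceless frames are excluded from both numerator and denominator of the
closing rate and reported as lost coverage.

**Frames, not seconds.** All duration thresholds are stored in frames,
faithful to the counter formulation; they implicitly assume a capture rate
(the default configuration is 25 fps). Users at other rates should scale
`yawn_frames`, `deep_yawn_frames`, `head_frame_threshold` and
`window_head_frames` by `fps / 25`, or set `window_seconds` and pass their
own frame thresholds.

# Numerical choices

- **DLT initialisation** solves the homogeneous 2n×12 system by SVD on
  undistorted normalised coordinates; scale is fixed by the rotation-row
  norms, sign by cheirality (mean model depth positive), and the rotation
  block is projected onto SO(3) by SVD. A ratio of the 11th to the 1st
  singular value below 1e−10 is reported as a singular configuration
  (collinear or otherwise degenerate correspondences).
- **Refinement** runs at most 100 Levenberg-damped Gauss–Newton steps on a
  Rodrigues-vector + translation parameterisation with central-difference
  Jacobians, stopping when the relative residual improvement falls below
  1e−12. On noise-free synthetic projections this reaches reprojection RMS
  near machine precision in a handful of iterations.
- **Rodrigues conversion** handles the two degenerate neighbourhoods
  explicitly: angles below 1e−10 return the zero vector; angles within
  1e−6 of π recover the axis from the symmetric part with sign fixing.
- **Distortion inversion** (for the DLT path under a distorting camera)
  uses 30 fixed-point iterations on the normalised plane, the standard
  approach for webcam-scale coefficients.
- **Degenerate ratio inputs** (zero eye-corner distance, zero inner-mouth
  width) raise errors rather than returning non-finite values; fully
  closed lids and lips return exactly 0.

# The simulator: what it emulates, what it does not

`render_stream` turns a `scenario_script` (fps, duration, events, noise,
seed) into a landmark stream plus ground truth. Its geometry is a
parametric 68-point 3D face (millimetres, camera-aligned axes at neutral:
x right, y down, z away from the camera, origin at the nose base, face
frontal at the identity rotation — so recovered Euler angles read directly
as pitch/yaw/roll with no reference-pose offset). The 14-point rigid model
shipped as `face_model_3d()` is exactly the pose subset of that face, with
plausible adult-average proportions; it is a synthetic fixture, not a
measured head, and pose accuracy in live use depends on how well a real
face matches whatever model is configured.

Event kinematics, chosen once:

- **Blinks**: 2-frame linear ramps around a full-depth plateau, eyelid
  points collapsing toward the lid line; closure depth is the scripted
  magnitude (default 1.0, EAR → ≈ 0).
- **Yawns**: a rectangular opening profile, so the scripted frame count is
  *exactly* the number of frames with MAR above threshold — this makes the
  duration state machine testable without off-by-one ambiguity.
- **Head events**: cosine ramps (up to 8 frames each side) to the target
  angle with a hold between, on one channel per event; the scripted angle
  trajectory *is* the Euler ground truth because deformations (blinks,
  yawns) are confined to landmarks outside the 14-point pose set, keeping
  the pose subset rigid at all times.
- **Face loss**: `no_face` events emit frames with the presence flag down.
- **Noise**: isotropic Gaussian per landmark coordinate, seeded; unit and
  acceptance tests run at 0, robustness tests at 0.5–1 px.

Ground truth is derived from the script and the noise-free geometry: true
per-frame EAR/MAR from the projected points, true Euler angles from the
scripted trajectory, per-window counts from the scripted events, and the
expected alert by applying the fused rule to those true aggregates.

What passing the simulator suite shows: the feature formulas, state
machines, episode segmentation, windowing and fusion are implemented
exactly, and the pose solver inverts the projection model to numerical
precision. What it cannot show: robustness to real detector behaviour —
landmark jitter is not isotropic Gaussian in practice, faces are not rigid
14-point objects, EAR/MAR baselines vary across people beyond the shape
parameters modelled here, and no photometric effects (lighting, occlusion,
motion blur) exist in the simulation. Thresholds that work on synthetic
streams are the method's published defaults, not personalised calibrations.

# Problem sizes used by the test suite

The suite favours many small deterministic scenarios over few large ones:
similarity-invariance properties run 1000 random transforms; the pose
round-trip and cross-solver comparisons run 100 random poses within ±45°;
end-to-end recovery runs 50 random zero-noise scenarios of one 12-second
window (300 frames) each, covering blinks, microsleeps, ordinary openings,
yawns, deep yawns, in- and out-of-range head excursions on all three
channels, and face-loss gaps. Window length for these scenarios is a
configuration choice (the alert clauses are frame-count based and carry
over unchanged); the defaults reproduce the one-minute, 25 fps setting.

# Known limitations

- EAR is not corrected for head rotation: a strong pitch foreshortens the
  eye opening and lowers the measured ratio. The method applies no such
  correction; at the pose magnitudes the state machines care about
  (±15°–35°) the effect stays well clear of the 0.20 threshold for an open
  eye, and the simulator's margins are chosen accordingly.
- A blink or yawn episode truncated by the start or end of the stream (or
  by a face-loss gap immediately adjacent) is not counted, since the
  completing transition was never observed.
- The PnP solver assumes a calibrated or approximately-calibrated camera;
  the uncalibrated default (focal length = image width, principal point at
  centre) is a common webcam approximation, and systematic intrinsics error
  biases the recovered angles.
- Exactly one face is assumed; multi-person scenes and identity tracking
  are out of scope, as are gaze estimation, expression recognition, and
  any on-screen rendering.
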