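---
title: "Methods: markerless upper-limb tracking and reach-task simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: markerless upper-limb tracking and reach-task simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(rehabtrack)
library(dplyr)
```

rehabtrack implements the computational core of a camera-based
virtual-rehabilitation workflow for the upper limb: two fixed cameras watch a
seated subject, a pose-estimation front end emits per-frame 2D keypoints for
6 arm joints and 42 finger joints, the server lifts them to 3D, smooths them,
and retargets them onto an avatar whose hand then plays standardized
reaching, mirrored-reaching and grasping games. The package reproduces every
stage after the neural-network detector, which it replaces with a synthetic
keypoint generator so the whole chain is testable end to end on a desk.

## The skeleton and its frames

The joint identity space has exactly 48 joints: shoulder, elbow and wrist on
each side (6 arm joints) and a 21-keypoint hand on each side (a hand root
plus four joints on each of five digits; 42 finger joints). The hand root is
deliberately a separate joint from the arm wrist -- the two are co-located in
the rest pose -- which keeps the 6/42 split of the tracked stream exact while
letting the digit chains root cleanly.

A `skeleton` is a tibble: one row per joint with its parent, bone length,
unit rest direction and rest position. Two skeletons ship with the package:
`"adult_user"` (a schematic seated adult, upper arm 0.30 m, forearm 0.28 m)
and `"avatar"` (15% longer limbs, so retargeting genuinely exercises limb
scaling). The world frame is right-handed, in meters, y-up, origin on the
floor midway between the cameras; the subject sits about 1.6 m from the
camera plane. Pose streams are long tibbles -- one row per joint per frame
with `time`, `joint`, `x`, `y`, `z`, `conf` -- so every stage composes with
ordinary dplyr verbs.

`validate_frame()` is a reporter, not a gate: it returns one row per violated
invariant (missing joints, non-finite positions carried with positive
confidence, bone lengths off the rest length beyond a relative tolerance)
and an empty tibble for a consistent frame.

```{r}
skel <- skeleton_default("adult_user")
validate_frame(skeleton_rest_pose(skel), skel)
```

## Synthetic capture: what it emulates and what it does not

`generate_motion()` produces ground-truth motion for one scripted movement.
The wrist follows a minimum-jerk trajectory, the standard smooth model of
point-to-point human reaching, whose peak speed is `1.875 * d / T` for a
reach of distance `d` over `T` seconds; an optional sinusoidal lateral
deviation (vanishing at both endpoints) emulates imperfect line tracking.
The elbow is placed by the same analytic two-bone solver used for the
avatar, with a fixed elbow-down swivel recorded as ground truth; digits
follow a per-joint flexion profile through forward kinematics, so every
generated frame is exactly consistent with the skeleton.

`render_keypoints()` projects each frame through a two-camera pinhole rig
and models the detector with isotropic Gaussian pixel noise plus independent
per-joint dropout (confidence 0), the failure mode occlusion produces. The
default rig matches the deployed geometry: cameras 1.4 m apart, 2.0 m above
the floor, aimed at a subject about 1.6 m away. Defaults chosen where the
deployment leaves them open: 30 Hz frame rate (consumer-camera typical),
1100 px focal length at 1280x1024. The front end's true noise magnitude is
not published, so sigma is a free simulation parameter; 1-2 px is a
realistic range for modern pose detectors at this image size.

The generator is deliberately idealized: noise is independent across frames
and joints (real detector error is temporally correlated and structured),
dropout is unconditional rather than occlusion-geometry driven, there is no
lens distortion, no detector bias, and exactly one person. Passing tests
therefore certify the geometry, filtering, kinematics and task logic -- not
robustness to real detector pathologies.

## Reconstruction

Two cameras only, so triangulation uses the ray-midpoint method: each
observation back-projects to a world ray, and the estimate is the midpoint
of the shortest segment between the rays, with the segment length returned
as a residual that serves as a per-joint quality score (zero for noiseless
input). A joint missing in either camera is marked confidence 0 and its
position left to the gap policy.

Smoothing defaults to the One-Euro filter, a causal adaptive low-pass filter
designed for low-latency pose streams: the cutoff is
`min_cutoff + beta * |velocity|`, so slow signals are smoothed hard while
fast motion passes with little lag. `min_cutoff` and the derivative cutoff
stay at the conventional 1 Hz. `beta` multiplies a velocity in m/s here, not
pixels/s, so its conventional pixel-scale value would pin the cutoff at
~1 Hz throughout a reach and the resulting lag (about 2 cm RMSE at reach
speed) would exceed the ~3 mm stereo noise it removes. The default is
therefore `beta = 20`: the cutoff rises by 20 Hz per m/s of estimated
speed, which on sigma = 2 px streams cuts reconstruction RMSE by roughly a
third and sits on a wide plateau (values 20-50 perform equally). Gap-filled
samples hold the last confident filtered value and their confidence decays
by 0.9 per frame, signalling staleness downstream; a gap before the first
confident sample back-fills from that sample at confidence 0.

```{r}
sc <- motion_script("reach",
  start = c(-0.05, 1.30, 1.58), target = c(0.15, 1.30, 1.40),
  duration = 1.5, fps = 30
)
gm <- generate_motion(sc, skel)
kp <- render_keypoints(gm, default_rig(), sigma = 2, dropout = 0.02, seed = 1)
rec <- filter_stream(fuse_streams(kp, default_rig()), filter_params("one_euro"))
inner_join(gm, rec, by = c("time", "joint"), suffix = c("", ".rec")) %>%
  summarise(rmse_mm = 1000 * sqrt(mean((x - x.rec)^2 + (y - y.rec)^2 + (z - z.rec)^2)))
```

## Avatar kinematics

Fingers use forward kinematics: each bone's orientation is the minimal
rotation from its rest direction to the measured direction
(`bone_orientation()`), converted to parent-local form and re-accumulated
along the avatar's chains (`finger_fk()`), which preserves avatar bone
lengths exactly. The antipodal case (measured direction exactly opposite
rest) has no unique minimal rotation; a half-turn about a fixed
perpendicular fallback axis keeps the mapping deterministic.

Arms use analytic two-bone inverse kinematics: the elbow interior angle
solves the law of cosines (`d = L1 = L2 = 0.3` m gives 60 degrees; full
extension gives 180), and the elbow sits in the plane spanned by the
shoulder-target axis and the measured elbow (the swivel constraint). Targets
outside the reachable annulus are clamped to its nearest point and flagged,
never rejected -- the avatar keeps extending toward the object while the
trial logic records the failure, which is the right behaviour for a
rehabilitation display. A swivel hint collinear with the axis falls back to
the previous frame's swivel, then to elbow-down. One terminological wrinkle:
"elbow angle" is monotone *increasing* in target distance as an interior
angle and *decreasing* as flexion; `arm_ik()` returns both (`elbow_angle`,
`flexion`) and the package asserts monotonicity on flexion.

`retarget()` scales wrist and elbow displacements about the shoulder by the
avatar/user total arm-length ratio (uniform per arm; the deployment says
nothing about size mismatch, and a uniform ratio preserves movement shape),
then solves IK on the avatar's lengths. `mode = "mirrored"` reflects the
user frame across the world midline first, swapping left/right labels, so a
left-limb movement drives the avatar's right limb -- mirrored-motion
therapy's contralateral mapping. Mirroring is an involution and an isometry,
and `retarget(f, "mirrored")` equals `retarget(mirror_pose(f), "normal")`
by construction.

## The trial state machine

All three paradigms are one deterministic, clock-driven state machine
(`trial_step()`), driven either by a recorded trace (`run_session()`) or by
a behaviour policy queried frame by frame (`simulate_session()`), which is
what lets the simulated subject react to randomly spawned targets. Per
trial: hold in the start area 1.5 s (blue to green), target spawns uniformly
in the calibrated reach area (gray; guide line from the start center),
reach it within 4 s and hold 1.5 s, score shown 1 s, return to start (blue
again). Grasp trials insert object 1 (grasp = proximity plus closed hand,
mean digit flexion over 60 degrees) and hold before object 2 spawns with
its line anchored at object 1 projected to the line's plane. Defaults the
deployment leaves unquantified: object proximity radius 0.04 m, start
radius 0.06 m, reach area 0.5 x 0.3 m at shoulder height (per-subject
calibration is a config input here).

Timing tie-breaks, decided once and tested: "reached within 4 s" is judged
on *first entry* into proximity, so a hold that completes after the 4 s mark
still finishes the trial; the timeout window does not restart if the hand
revisits the start area; unfinished trials still require the return leg
before the next trial begins. Sessions are bit-identical given the same
configuration, seed and trace.

## Outcome measures

Scores use the deployed formula: each frame of the movement window (first
exit from the start area until reach or timeout) maps the hand center onto
the horizontal plane at the guide line's height, takes perpendicular
distance to the line segment, and averages per frame (the natural reading
of a per-frame mean; a duration-weighted alternative would differ only
under variable frame rates). Then

    score = (0.1 - average distance) * 1000

clamped to [0, 100]: exact tracking scores 100, and the score reaches 0 at
a 10 cm mean deviation -- the formula only makes sense with distances in
meters, which fixes the unit convention. Unfinished trials score 0 (their
distances are still computed for diagnostics). Game performance is the sum
over the session's 30 trials, maximum 3000; the unfinished rate is the
unfinished fraction; peak velocity is the maximum of central-difference
speeds smoothed by a 5-sample moving average over the movement window.

```{r}
cfg <- task_config(kind = "normal", seed = 7)
session <- simulate_session(cfg, policy_line_follower())
glance(session)
```

A perfect line follower recovers the theoretical ceiling (game performance
3000), and `policy_hold_start()` recovers the timeout constants -- these are
the package's acceptance anchors, recomputed from scratch by
`scripts/acceptance.R`.

## Problem sizes and limitations

Simulated sessions run at 30 Hz (a 30-trial session is roughly 5,000-6,000
frames and takes under a second); reconstruction examples use 1-2 s clips,
which is ample for the geometric properties being verified since every
stage is stationary in time. Known limitations: no torso or head joints, no
joint-limit model beyond the elbow's interior angle in [0, pi], no
multi-person disambiguation, no camera auto-calibration, and the human-study
outcomes of the original deployment (embodiment questionnaires, clinical
motor scores) are out of computational scope. Whether 3D lifting belongs
inside the detector or after it is a systems choice; this implementation
performs explicit stereo triangulation, which the two-camera rig supports
directly.
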