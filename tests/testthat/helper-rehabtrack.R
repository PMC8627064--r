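# shared fixtures, built in code
user_skel <- skeleton_default("adult_user")
avatar_skel <- skeleton_default("avatar")
rig <- default_rig()

# a short left-arm reach across the default reach area
reach_script <- function(duration = 2, fps = 30, amplitude = 0, ...) {
  motion_script(
    "reach",
    start = c(-0.05, 1.30, 1.58), target = c(0.15, 1.30, 1.40),
    duration = duration, fps = fps, side = "left",
    lateral_amplitude = amplitude, ...
  )
}

# random but skeleton-consistent frame: retargets rest pose noise through FK
random_valid_frame <- function(seed) {
  set.seed(seed)
  sc <- motion_script(
    "reach",
    start = c(-0.05, 1.30, 1.58),
    target = c(runif(1, -0.2, 0.2), 1.30, runif(1, 1.35, 1.55)),
    duration = 1, fps = 4, side = "left",
    flexion = function(tau) runif(1, 0, 1) * tau
  )
  gm <- generate_motion(sc, user_skel)
  gm[gm$time == max(gm$time), ]
}

frame_at <- function(frames, t) frames[abs(frames$time - t) < 1e-9, ]

pos_of <- function(frame, joint) {
  i <- match(joint, frame$joint)
  c(frame$x[i], frame$y[i], frame$z[i])
}

small_cfg <- function(...) {
  args <- utils::modifyList(
    list(trials = 4L, limb_switch = 2L, seed = 7L),
    list(...)
  )
  do.call(task_config, args)
}
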