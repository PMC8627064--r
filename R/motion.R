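#' Describe a synthetic upper-limb motion
#'
#' A motion script parameterizes one synthetic movement: the wrist travels
#' from `start` to `target` along a minimum-jerk trajectory (the standard
#' smooth model of point-to-point human reaching), optionally with a
#' sinusoidal lateral deviation perpendicular to the line that vanishes at
#' both endpoints, while the digits follow a flexion profile. The script also
#' carries the keypoint observation model (pixel noise and per-joint dropout)
#' used when the motion is rendered into the two cameras.
#'
#' @param kind `"reach"`, `"mirrored_reach"` or `"grasp"`. The kinds share
#'   the same kinematic model; `"mirrored_reach"` marks streams meant to be
#'   retargeted in mirrored mode, `"grasp"` defaults to a closing finger
#'   flexion profile.
#' @param start,target Wrist start and end points (m, world frame).
#' @param duration Movement duration (s), > 0.
#' @param fps Frame rate (Hz), > 0; default 30 (consumer-camera typical).
#' @param side Which arm moves, `"left"` or `"right"`.
#' @param lateral_amplitude Amplitude (m) of the sinusoidal deviation
#'   perpendicular to the straight line; 0 gives a perfectly straight reach.
#' @param flexion `NULL` (digits stay at rest; for `"grasp"` a closing ramp
#'   is substituted) or a function of normalized time tau in \[0, 1\]
#'   returning the per-joint digit flexion angle (rad).
#' @param sigma_px Isotropic Gaussian keypoint noise (px), >= 0.
#' @param dropout Per-joint per-camera per-frame dropout probability.
#' @param seed Integer seed making the rendered keypoint streams reproducible.
#' @return An object of class `"motion_script"`.
#' @export
motion_script <- function(kind = c("reach", "mirrored_reach", "grasp"),
                          start, target, duration = 2, fps = 30,
                          side = c("left", "right"),
                          lateral_amplitude = 0, flexion = NULL,
                          sigma_px = 0, dropout = 0, seed = 1L) {
  kind <- match.arg(kind)
  side <- match.arg(side)
  if (duration <= 0 || fps <= 0 || sigma_px < 0 || dropout < 0 || dropout > 1) {
    abort("invalid motion script parameters", class = "rehabtrack_invalid_argument")
  }
  if (kind == "grasp" && is.null(flexion)) flexion <- flexion_grasp_profile()
  structure(
    list(
      kind = kind, start = as.numeric(start), target = as.numeric(target),
      duration = duration, fps = fps, side = side,
      lateral_amplitude = lateral_amplitude, flexion = flexion,
      sigma_px = sigma_px, dropout = dropout, seed = as.integer(seed)
    ),
    class = "motion_script"
  )
}

#' Digit flexion ramp used for synthetic grasps
#'
#' Flexion stays zero while the hand travels and ramps smoothly to
#' `max_angle` per joint over the last part of the movement, closing the
#' hand as it arrives at the object.
#'
#' @param max_angle Final per-joint flexion (rad).
#' @param onset Normalized time at which closing starts.
#' @return A function of tau in \[0, 1\].
#' @export
flexion_grasp_profile <- function(max_angle = 1.1, onset = 0.55) {
  force(max_angle)
  force(onset)
  function(tau) {
    u <- pmin(1, pmax(0, (tau - onset) / (1 - onset)))
    max_angle * min_jerk_s(u)
  }
}

# positions of one hand (21 joints, skeleton row order) given the hand root
# position and a uniform per-joint digit flexion angle; the base (root->MCP)
# bones stay at rest orientation, flexion is applied as equal local rotations
# at the three phalanx joints of each digit so the fingers curl
hand_points <- function(skel, side, root_pos, flex_angle = 0) {
  hand <- skel[skel$category == "hand" & skel$side == side, ]
  out <- matrix(NA_real_, nrow(hand), 3, dimnames = list(hand$joint, NULL))
  root_name <- paste0(side, "_hand_root")
  out[root_name, ] <- root_pos
  for (dg in c("thumb", "index", "middle", "ring", "little")) {
    chain <- hand[!is.na(hand$digit) & hand$digit == dg, ]
    chain <- chain[order(chain$chain_index), ]
    p <- root_pos
    q <- quat_identity()
    for (k in seq_len(nrow(chain))) {
      dir <- c(chain$dir_x[k], chain$dir_y[k], chain$dir_z[k])
      if (k >= 2 && flex_angle != 0) {
        q <- quat_mul(q, quat_axis_angle(v_perp(dir), flex_angle))
      }
      p <- p + quat_rotate(q, dir * chain$length[k])
      out[chain$joint[k], ] <- p
    }
  }
  out
}

#' Generate ground-truth 3D motion from a script
#'
#' The scripted wrist follows a minimum-jerk trajectory from `start` to
#' `target` plus the configured lateral sinusoid; the elbow and shoulder are
#' placed consistently with the skeleton's bone lengths by analytic two-bone
#' inverse kinematics with a fixed elbow-down swivel; digits follow the
#' flexion profile through forward kinematics; the contralateral limb holds
#' the rest pose. Every generated frame passes [validate_frame()] with zero
#' violations, and generation is deterministic.
#'
#' @param script A [motion_script()].
#' @param skel The subject skeleton (default [skeleton_default()]
#'   `"adult_user"`).
#' @return A pose tibble (`time`, `joint`, `x`, `y`, `z`, `conf`), 48 joints
#'   per frame, `floor(duration * fps) + 1` frames.
#' @export
generate_motion <- function(script, skel = skeleton_default("adult_user")) {
  stopifnot(inherits(script, "motion_script"))
  side <- script$side
  sh <- rest_positions(skel)[paste0(side, "_shoulder"), ]
  L <- arm_lengths(skel, side)
  nf <- floor(script$duration * script$fps) + 1
  times <- (seq_len(nf) - 1) / script$fps
  tau <- times / script$duration

  line <- script$target - script$start
  perp <- if (script$lateral_amplitude != 0) {
    a <- v_cross(line, c(0, 1, 0))
    if (v_norm(a) < 1e-9) a <- v_cross(line, c(0, 0, 1))
    v_unit(a)
  } else {
    c(0, 0, 0)
  }
  s <- min_jerk_s(tau)
  wav <- script$lateral_amplitude * sin(2 * pi * tau)
  wrist <- matrix(script$start, nf, 3, byrow = TRUE) +
    outer(s, line) + outer(wav, perp)

  d <- sqrt(rowSums((wrist - matrix(sh, nf, 3, byrow = TRUE))^2))
  if (any(d > sum(L) - 1e-9) || any(d < abs(diff(L)) + 1e-9)) {
    abort("scripted wrist path leaves the arm's reachable annulus",
      class = "rehabtrack_unreachable_script"
    )
  }

  rest <- rest_positions(skel)
  static_joints <- skel$joint[skel$side != side]
  flex <- script$flexion
  frames <- vector("list", nf)
  for (i in seq_len(nf)) {
    ik <- arm_ik(sh, wrist[i, ], elbow_hint = NULL, L1 = L[1], L2 = L[2])
    ang <- if (is.null(flex)) 0 else flex(tau[i])
    hp <- hand_points(skel, side, wrist[i, ], ang)
    mv <- rbind(
      matrix(c(sh, ik$elbow_pos, wrist[i, ]),
        3, 3,
        byrow = TRUE,
        dimnames = list(paste0(side, c("_shoulder", "_elbow", "_wrist")), NULL)
      ),
      hp
    )
    pos <- rbind(mv, rest[static_joints, , drop = FALSE])
    pos <- pos[skel$joint, , drop = FALSE] # canonical joint order
    frames[[i]] <- tibble(
      time = times[i], joint = rownames(pos),
      x = unname(pos[, 1]), y = unname(pos[, 2]), z = unname(pos[, 3]),
      conf = 1
    )
  }
  bind_rows(frames)
}

#' Render a 3D stream into two-camera keypoint observations
#'
#' Emulates the markerless pose-estimation front end: each joint is projected
#' through both pinhole cameras, perturbed by isotropic Gaussian pixel noise,
#' and dropped (confidence 0, coordinates `NA`) with the given probability to
#' model occlusion and missed detections. With `sigma = 0` and `dropout = 0`
#' the output equals the exact projections. Given the same seed the output is
#' bit-identical.
#'
#' @param frames A 3D pose tibble, e.g. from [generate_motion()].
#' @param rig A `"camera_rig"` (default [default_rig()]).
#' @param sigma Pixel noise standard deviation per axis (px).
#' @param dropout Per-joint per-camera per-frame dropout probability.
#' @param seed Optional integer seed; the caller's RNG state is restored on
#'   exit.
#' @return A keypoint tibble with columns `time`, `camera`, `joint`, `u`,
#'   `v`, `conf`.
#' @export
render_keypoints <- function(frames, rig = default_rig(), sigma = 0,
                             dropout = 0, seed = NULL) {
  if (sigma < 0 || dropout < 0 || dropout > 1) {
    abort("invalid noise model parameters", class = "rehabtrack_invalid_argument")
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(
      if (!is.null(old)) assign(".Random.seed", old, globalenv()),
      add = TRUE
    )
    set.seed(seed)
  }
  pts <- as.matrix(frames[, c("x", "y", "z")])
  n <- nrow(pts)
  render_one <- function(cam) {
    uv <- .project_matrix(cam, pts)
    if (sigma > 0) uv <- uv + matrix(rnorm(2 * n, 0, sigma), n, 2)
    drop <- if (dropout > 0) runif(n) < dropout else rep(FALSE, n)
    tibble(
      time = frames$time, camera = cam$id, joint = frames$joint,
      u = ifelse(drop, NA_real_, uv[, 1]),
      v = ifelse(drop, NA_real_, uv[, 2]),
      conf = ifelse(drop, 0, frames$conf)
    )
  }
  bind_rows(render_one(rig$a), render_one(rig$b))
}
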