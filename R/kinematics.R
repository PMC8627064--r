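#' Orientation of a bone from measured endpoint positions
#'
#' Returns the minimal rotation (unit quaternion, `c(w, x, y, z)`) carrying
#' the bone's rest direction onto the measured parent-to-child direction.
#' When the measured direction is exactly opposite the rest direction the
#' minimal-rotation axis is undefined; a half-turn about `fallback_axis`
#' (default: a fixed deterministic perpendicular of the rest direction) is
#' returned instead, keeping the mapping deterministic.
#'
#' @param parent_pos,child_pos Measured joint positions (m).
#' @param rest_dir Rest bone direction (unit vector).
#' @param fallback_axis Axis used for the antipodal tie-break.
#' @return Unit quaternion (length-4 numeric).
#' @export
bone_orientation <- function(parent_pos, child_pos, rest_dir,
                             fallback_axis = NULL) {
  d <- child_pos - parent_pos
  if (v_norm(d) < 1e-12) {
    abort("bone endpoints coincide: orientation undefined",
      class = "rehabtrack_zero_length_bone"
    )
  }
  quat_between(v_unit(rest_dir), d / v_norm(d), fallback_axis)
}

# ordered hand bones (rows of skel with a parent) for one side
hand_bones <- function(skel, side) {
  skel[skel$category == "hand" & skel$side == side & !is.na(skel$parent), ]
}

#' Local hand-bone orientations measured from a pose frame
#'
#' Walks each digit chain root-to-tip, computes the world rotation of each
#' bone with [bone_orientation()], and converts it to a rotation local to the
#' parent bone, the representation consumed by [finger_fk()]. Running
#' [finger_fk()] on the result with the same skeleton reproduces the measured
#' joint positions (up to bone-length differences).
#'
#' @param frame A single-timestamp 3D pose tibble containing the hand joints
#'   of `side`.
#' @param skel The skeleton the frame is measured on.
#' @param side `"left"` or `"right"`.
#' @return A tibble with columns `joint` (the bone's child joint), `qw`,
#'   `qx`, `qy`, `qz`.
#' @export
hand_orientations <- function(frame, skel, side = c("left", "right")) {
  side <- match.arg(side)
  pos <- frame_positions(frame)
  bones <- hand_bones(skel, side)
  rows <- vector("list", nrow(bones))
  n <- 0
  for (dg in c("thumb", "index", "middle", "ring", "little")) {
    chain <- bones[!is.na(bones$digit) & bones$digit == dg, ]
    chain <- chain[order(chain$chain_index), ]
    q_parent <- quat_identity()
    for (k in seq_len(nrow(chain))) {
      jn <- chain$joint[k]
      pn <- chain$parent[k]
      if (!(jn %in% rownames(pos)) || !(pn %in% rownames(pos))) {
        abort(sprintf("frame is missing hand joint '%s' or '%s'", jn, pn),
          class = "rehabtrack_incomplete_pose"
        )
      }
      w <- bone_orientation(
        pos[pn, ], pos[jn, ],
        c(chain$dir_x[k], chain$dir_y[k], chain$dir_z[k])
      )
      loc <- quat_mul(quat_conj(q_parent), w)
      q_parent <- w
      n <- n + 1
      rows[[n]] <- tibble(
        joint = jn, qw = loc[1], qx = loc[2], qy = loc[3], qz = loc[4]
      )
    }
  }
  bind_rows(rows)
}

#' Forward kinematics of the finger chains
#'
#' Accumulates positions root-to-tip: each bone's local orientation is
#' composed onto its parent's world orientation and the child joint is placed
#' at `parent_position + world_rotation (rest_dir * length)`, so avatar bone
#' lengths are preserved exactly by construction. With all-identity
#' orientations the fingers stand in the rest pose translated to
#' `hand_root_pos`.
#'
#' @param orientations Local per-bone orientations as returned by
#'   [hand_orientations()]; every bone of the side's five digit chains must
#'   be present.
#' @param skel The skeleton whose bone lengths are used (the avatar's, when
#'   retargeting).
#' @param hand_root_pos World position of the hand root (m).
#' @param side `"left"` or `"right"`.
#' @return A tibble (`joint`, `x`, `y`, `z`) for the 21 hand joints.
#' @export
finger_fk <- function(orientations, skel, hand_root_pos,
                      side = c("left", "right")) {
  side <- match.arg(side)
  bones <- hand_bones(skel, side)
  missing <- setdiff(bones$joint, orientations$joint)
  if (length(missing) > 0) {
    abort(
      sprintf(
        "incomplete hand pose: missing orientation for %s",
        paste(missing, collapse = ", ")
      ),
      class = "rehabtrack_incomplete_pose"
    )
  }
  qs <- as.matrix(orientations[, c("qw", "qx", "qy", "qz")])
  rownames(qs) <- orientations$joint
  out <- matrix(NA_real_, nrow(bones) + 1, 3,
    dimnames = list(c(paste0(side, "_hand_root"), bones$joint), NULL)
  )
  out[1, ] <- hand_root_pos
  for (dg in c("thumb", "index", "middle", "ring", "little")) {
    chain <- bones[!is.na(bones$digit) & bones$digit == dg, ]
    chain <- chain[order(chain$chain_index), ]
    q <- quat_identity()
    p <- hand_root_pos
    for (k in seq_len(nrow(chain))) {
      q <- quat_mul(q, qs[chain$joint[k], ])
      p <- p + quat_rotate(q, c(chain$dir_x[k], chain$dir_y[k], chain$dir_z[k]) *
        chain$length[k])
      out[chain$joint[k], ] <- p
    }
  }
  tibble(
    joint = rownames(out),
    x = unname(out[, 1]), y = unname(out[, 2]), z = unname(out[, 3])
  )
}

#' Analytic two-bone arm inverse kinematics
#'
#' Solves the shoulder-elbow-wrist chain in closed form. When the target
#' distance `d` lies in the reachable annulus `[|L1 - L2|, L1 + L2]`, the
#' elbow interior angle solves the law of cosines `d^2 = L1^2 + L2^2 -
#' 2 L1 L2 cos(theta)` and the elbow is placed in the plane spanned by the
#' shoulder-target axis and `elbow_hint` (the swivel constraint, normally the
#' measured elbow). Targets outside the annulus are clamped to its nearest
#' point and flagged unreachable rather than rejected: the avatar keeps
#' extending toward the object while the trial logic records the failure.
#' Applying forward kinematics to the solution reproduces the (clamped)
#' wrist target to well below 1e-9 m.
#'
#' A hint collinear with the shoulder-target axis leaves the swivel
#' undefined; `prev_swivel` (continuity with the previous frame) is used if
#' supplied, else `fallback_swivel` (elbow-down by default). This is a
#' documented fallback, never an error.
#'
#' @param shoulder_pos Shoulder position (m).
#' @param wrist_target Requested wrist position (m).
#' @param elbow_hint Measured elbow position fixing the swivel plane, or
#'   `NULL` to use the fallback directly.
#' @param L1,L2 Upper-arm and forearm lengths (m), > 0.
#' @param fallback_swivel Default swivel direction (world frame).
#' @param prev_swivel Unit swivel direction from the previous frame, if any.
#' @param upper_rest_dir Rest direction of the upper-arm bone, used to report
#'   the shoulder orientation quaternion.
#' @return A list of class `"ik_solution"`: `elbow_angle` (interior angle,
#'   rad, in \[0, pi\]), `flexion` (`pi - elbow_angle`), `reachable`,
#'   `target_clamped`, `elbow_pos`, `wrist_pos` (equal to `target_clamped`),
#'   `swivel`, `shoulder_q`, `L1`, `L2`.
#' @examples
#' s <- arm_ik(c(0, 0, 0), c(0.3, 0, 0), c(0.1, -0.2, 0), 0.3, 0.3)
#' s$elbow_angle * 180 / pi # 60 degrees
#' @export
arm_ik <- function(shoulder_pos, wrist_target, elbow_hint = NULL,
                   L1, L2, fallback_swivel = c(0, -1, 0), prev_swivel = NULL,
                   upper_rest_dir = c(0, -1, 0)) {
  if (L1 <= 0 || L2 <= 0) {
    abort("bone lengths must be positive", class = "rehabtrack_invalid_argument")
  }
  delta <- wrist_target - shoulder_pos
  d <- v_norm(delta)
  lo <- abs(L1 - L2)
  hi <- L1 + L2
  reachable <- d >= lo - 1e-12 && d <= hi + 1e-12
  d_c <- min(max(d, lo), hi)
  axis <- if (d > 1e-12) delta / d else c(0, -1, 0)
  if (d_c < 1e-12) d_c <- 1e-12 # L1 == L2 and target at the shoulder
  target_c <- shoulder_pos + axis * d_c

  cos_theta <- (L1^2 + L2^2 - d_c^2) / (2 * L1 * L2)
  elbow_angle <- acos(min(1, max(-1, cos_theta)))

  a <- (L1^2 + d_c^2 - L2^2) / (2 * d_c)
  r <- sqrt(max(L1^2 - a^2, 0))

  pick_swivel <- function(v) {
    if (is.null(v)) {
      return(NULL)
    }
    perp <- v - sum(v * axis) * axis
    if (v_norm(perp) < 1e-9) NULL else v_unit(perp)
  }
  sw <- NULL
  if (!is.null(elbow_hint)) sw <- pick_swivel(elbow_hint - shoulder_pos)
  if (is.null(sw)) sw <- pick_swivel(prev_swivel)
  if (is.null(sw)) sw <- pick_swivel(fallback_swivel)
  if (is.null(sw)) sw <- v_perp(axis)

  elbow <- shoulder_pos + a * axis + r * sw
  structure(
    list(
      elbow_angle = elbow_angle, flexion = pi - elbow_angle,
      reachable = reachable, target = wrist_target, target_clamped = target_c,
      elbow_pos = elbow, wrist_pos = target_c, swivel = sw,
      shoulder_q = quat_between(v_unit(upper_rest_dir), v_unit(elbow - shoulder_pos)),
      L1 = L1, L2 = L2
    ),
    class = "ik_solution"
  )
}

#' @export
print.ik_solution <- function(x, ...) {
  cat(sprintf(
    "<ik_solution> elbow %.1f deg, %s target (%.3f, %.3f, %.3f)\n",
    x$elbow_angle * 180 / pi,
    if (x$reachable) "reachable" else "clamped",
    x$target_clamped[1], x$target_clamped[2], x$target_clamped[3]
  ))
  invisible(x)
}

# named n x 3 position matrix from a single-timestamp pose tibble
frame_positions <- function(frame) {
  m <- as.matrix(frame[, c("x", "y", "z")])
  dimnames(m) <- list(frame$joint, NULL)
  m
}

#' Retarget a measured pose frame onto the avatar skeleton
#'
#' Transfers a user's measured upper-limb pose to the avatar: wrist targets
#' are scaled about the avatar shoulder by the avatar/user total arm-length
#' ratio, each arm is solved with [arm_ik()] using the (equally scaled)
#' measured elbow as the swivel hint, and the fingers are driven by
#' [bone_orientation()] + [finger_fk()], so every avatar bone keeps its exact
#' length. In `"mirrored"` mode the user frame is first reflected with
#' [mirror_pose()] across the world midline, mapping each limb onto the
#' avatar's contralateral limb.
#'
#' @param frame A single-timestamp 3D pose tibble with all 48 joints.
#' @param user_skel Skeleton the frame was measured on.
#' @param avatar_skel Skeleton being driven.
#' @param mode `"normal"` or `"mirrored"`.
#' @param prev_swivel Optional named list (`left`, `right`) of previous-frame
#'   swivel directions for continuity in degenerate configurations.
#' @return An object of class `"avatar_pose"`: `time`, `mode`, `positions`
#'   (tibble `joint`, `x`, `y`, `z` for all 48 avatar joints),
#'   `orientations` (tibble of world per-bone quaternions) and `ik` (the two
#'   `"ik_solution"`s).
#' @export
retarget <- function(frame, user_skel = skeleton_default("adult_user"),
                     avatar_skel = skeleton_default("avatar"),
                     mode = c("normal", "mirrored"), prev_swivel = NULL) {
  mode <- match.arg(mode)
  if (length(unique(frame$time)) != 1) {
    abort("retarget() expects a single-timestamp frame; see retarget_stream()",
      class = "rehabtrack_invalid_argument"
    )
  }
  if (mode == "mirrored") frame <- mirror_pose(frame)
  missing <- setdiff(user_skel$joint, frame$joint)
  if (length(missing) > 0) {
    abort(
      sprintf("incomplete pose: missing %s", paste(missing, collapse = ", ")),
      class = "rehabtrack_incomplete_pose"
    )
  }
  pos <- frame_positions(frame)
  a_rest <- rest_positions(avatar_skel)

  positions <- list()
  orient <- list()
  ik_out <- list()
  for (side in c("left", "right")) {
    Lu <- arm_lengths(user_skel, side)
    La <- arm_lengths(avatar_skel, side)
    ratio <- sum(La) / sum(Lu)
    us <- pos[paste0(side, "_shoulder"), ]
    as_ <- a_rest[paste0(side, "_shoulder"), ]
    target <- as_ + ratio * (pos[paste0(side, "_wrist"), ] - us)
    hint <- as_ + ratio * (pos[paste0(side, "_elbow"), ] - us)
    ik <- arm_ik(as_, target, hint,
      L1 = La[1], L2 = La[2],
      prev_swivel = prev_swivel[[side]]
    )
    ik_out[[side]] <- ik
    hand <- finger_fk(
      hand_orientations(frame, user_skel, side),
      avatar_skel, ik$wrist_pos, side
    )
    positions[[side]] <- bind_rows(
      tibble(
        joint = paste0(side, c("_shoulder", "_elbow", "_wrist")),
        x = c(as_[1], ik$elbow_pos[1], ik$wrist_pos[1]),
        y = c(as_[2], ik$elbow_pos[2], ik$wrist_pos[2]),
        z = c(as_[3], ik$elbow_pos[3], ik$wrist_pos[3])
      ),
      hand
    )
    fore_dir <- v_unit(ik$wrist_pos - ik$elbow_pos)
    orient[[side]] <- bind_rows(
      tibble(
        bone = paste0(side, c("_elbow", "_wrist")),
        qw = c(ik$shoulder_q[1], quat_between(c(0, -1, 0), fore_dir)[1]),
        qx = c(ik$shoulder_q[2], quat_between(c(0, -1, 0), fore_dir)[2]),
        qy = c(ik$shoulder_q[3], quat_between(c(0, -1, 0), fore_dir)[3]),
        qz = c(ik$shoulder_q[4], quat_between(c(0, -1, 0), fore_dir)[4])
      ),
      world_hand_orientations(frame, user_skel, side)
    )
  }
  positions <- bind_rows(positions)
  positions <- positions[match(avatar_skel$joint, positions$joint), ]
  structure(
    list(
      time = frame$time[1], mode = mode, positions = positions,
      orientations = bind_rows(orient), ik = ik_out
    ),
    class = "avatar_pose"
  )
}

# world (not local) hand bone orientations, for the avatar pose record
world_hand_orientations <- function(frame, skel, side) {
  pos <- frame_positions(frame)
  bones <- hand_bones(skel, side)
  qs <- matrix(NA_real_, nrow(bones), 4)
  for (k in seq_len(nrow(bones))) {
    qs[k, ] <- bone_orientation(
      pos[bones$parent[k], ], pos[bones$joint[k], ],
      c(bones$dir_x[k], bones$dir_y[k], bones$dir_z[k])
    )
  }
  tibble(bone = bones$joint, qw = qs[, 1], qx = qs[, 2], qy = qs[, 3], qz = qs[, 4])
}

#' @export
print.avatar_pose <- function(x, ...) {
  cat(sprintf(
    "<avatar_pose> t = %.3f s, mode %s, %d joints\n",
    x$time, x$mode, nrow(x$positions)
  ))
  invisible(x)
}

#' Retarget a whole pose stream
#'
#' Applies [retarget()] frame by frame, carrying each arm's swivel direction
#' forward so degenerate frames reuse the previous swivel.
#'
#' @inheritParams retarget
#' @param frames A multi-frame 3D pose tibble.
#' @return A tibble (`time`, `joint`, `x`, `y`, `z`) of avatar joint
#'   positions.
#' @export
retarget_stream <- function(frames, user_skel = skeleton_default("adult_user"),
                            avatar_skel = skeleton_default("avatar"),
                            mode = c("normal", "mirrored")) {
  mode <- match.arg(mode)
  prev <- NULL
  out <- lapply(split(frames, frames$time), function(fr) {
    ap <- retarget(fr, user_skel, avatar_skel, mode, prev_swivel = prev)
    prev <<- list(left = ap$ik$left$swivel, right = ap$ik$right$swivel)
    mutate(ap$positions, time = ap$time, .before = 1)
  })
  bind_rows(out[order(as.numeric(names(out)))])
}

#' Mean digit flexion and grasp detection
#'
#' `mean_digit_flexion()` estimates how closed a hand is as the mean angle
#' between consecutive bone directions along the five digit chains;
#' `grasp_closed()` thresholds it (default 60 degrees), the criterion the
#' grasping task uses to decide that the hand is holding the object.
#'
#' @param frame A single-timestamp pose tibble containing the side's hand.
#' @param skel The skeleton the frame is measured on.
#' @param side `"left"` or `"right"`.
#' @param threshold Flexion threshold (rad) for `grasp_closed()`.
#' @return `mean_digit_flexion()`: radians; `grasp_closed()`: logical.
#' @export
mean_digit_flexion <- function(frame, skel, side = c("left", "right")) {
  side <- match.arg(side)
  pos <- frame_positions(frame)
  bones <- hand_bones(skel, side)
  angs <- c()
  for (dg in c("thumb", "index", "middle", "ring", "little")) {
    chain <- bones[!is.na(bones$digit) & bones$digit == dg, ]
    chain <- chain[order(chain$chain_index), ]
    dirs <- t(vapply(seq_len(nrow(chain)), function(k) {
      v_unit(pos[chain$joint[k], ] - pos[chain$parent[k], ])
    }, numeric(3)))
    for (k in 2:nrow(dirs)) {
      angs <- c(angs, acos(min(1, max(-1, sum(dirs[k - 1, ] * dirs[k, ])))))
    }
  }
  mean(angs)
}

#' @rdname mean_digit_flexion
#' @export
grasp_closed <- function(frame, skel, side = c("left", "right"),
                         threshold = pi / 3) {
  mean_digit_flexion(frame, skel, side) > threshold
}
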