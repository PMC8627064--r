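#' The upper-limb joint identity space
#'
#' The tracked stream carries 48 joints: 6 arm joints (shoulder, elbow, wrist
#' on each side) and 42 finger joints laid out as the common 21-keypoint hand
#' model (one hand root plus four joints on each of the five digits, per
#' hand). The hand root is a distinct joint from the arm wrist; the two are
#' co-located in the rest pose so that the 6/42 split stays exact.
#'
#' @return A tibble with one row per joint and columns `joint`, `category`
#'   (`"arm"` or `"hand"`), `side` (`"left"` or `"right"`), `digit`
#'   (`NA` for arm joints and the hand root) and `chain_index` (1-4 along a
#'   digit, `NA` otherwise).
#' @examples
#' dplyr::count(joint_table(), category)
#' @export
joint_table <- function() {
  digits <- c("thumb", "index", "middle", "ring", "little")
  one_side <- function(side) {
    arm <- tibble(
      joint = paste(side, c("shoulder", "elbow", "wrist"), sep = "_"),
      category = "arm", side = side, digit = NA_character_,
      chain_index = NA_integer_
    )
    hand <- tibble(
      joint = paste(side, "hand_root", sep = "_"),
      category = "hand", side = side, digit = NA_character_,
      chain_index = NA_integer_
    )
    fingers <- tidyr::expand_grid(digit = digits, chain_index = 1:4) %>%
      mutate(
        joint = paste(side, .data$digit, .data$chain_index, sep = "_"),
        category = "hand", side = side
      ) %>%
      select("joint", "category", "side", "digit", "chain_index")
    bind_rows(arm, hand, fingers)
  }
  bind_rows(one_side("left"), one_side("right"))
}

#' Build an upper-limb skeleton definition
#'
#' A skeleton is a tibble with one row per joint holding the topology
#' (`parent`), the rest bone geometry (`length` in meters and the unit rest
#' direction `dir_x/dir_y/dir_z` from parent to child) and the rest-pose
#' position `rest_x/rest_y/rest_z` in the world frame. The world frame is
#' right-handed, in meters, y-up, with its origin on the floor at the midpoint
#' between the two capture cameras; the subject faces the cameras from about
#' 1.6 m away.
#'
#' Roots (the two shoulders and the two hand roots) have no parent and carry
#' `NA` bone geometry; each arm chain is shoulder-elbow-wrist and each digit
#' chain roots at the hand root. Hand roots are co-located with the wrists in
#' the rest pose.
#'
#' @param name Label stored on the skeleton.
#' @param shoulder_width Distance between the shoulders (m).
#' @param shoulder_height Shoulder height above the floor (m).
#' @param body_z Distance of the shoulder line from the camera plane (m).
#' @param upper_arm,forearm Arm segment lengths (m).
#' @param hand_scale Multiplier applied to all hand segment lengths.
#' @return A tibble of class `"skeleton"`.
#' @seealso [skeleton_default()] for the shipped user and avatar skeletons.
#' @export
skeleton_build <- function(name = "custom",
                           shoulder_width = 0.40,
                           shoulder_height = 1.30,
                           body_z = 1.65,
                           upper_arm = 0.30,
                           forearm = 0.28,
                           hand_scale = 1.0) {
  stopifnot(
    shoulder_width > 0, upper_arm > 0, forearm > 0, hand_scale > 0
  )
  digits <- c("thumb", "index", "middle", "ring", "little")
  lat_left <- c(thumb = 0.045, index = 0.022, middle = 0, ring = -0.022, little = -0.045)
  seg_mult <- c(thumb = 0.90, index = 1.00, middle = 1.08, ring = 0.98, little = 0.82)
  base_drop <- 0.085 * hand_scale
  phal <- c(0.048, 0.030, 0.024) * hand_scale

  rows <- list()
  add <- function(joint, category, side, digit, chain_index, parent, rest, dir, len) {
    rows[[length(rows) + 1]] <<- tibble(
      joint = joint, category = category, side = side,
      digit = digit, chain_index = chain_index, parent = parent,
      length = len, dir_x = dir[1], dir_y = dir[2], dir_z = dir[3],
      rest_x = rest[1], rest_y = rest[2], rest_z = rest[3]
    )
    rest
  }

  for (side in c("left", "right")) {
    sgn <- if (side == "left") -1 else 1
    sh <- c(sgn * shoulder_width / 2, shoulder_height, body_z)
    add(paste0(side, "_shoulder"), "arm", side, NA_character_, NA_integer_,
      NA_character_, sh, c(NA_real_, NA_real_, NA_real_), NA_real_)
    el <- sh + c(0, -upper_arm, 0)
    add(paste0(side, "_elbow"), "arm", side, NA_character_, NA_integer_,
      paste0(side, "_shoulder"), el, c(0, -1, 0), upper_arm)
    wr <- el + c(0, -forearm, 0)
    add(paste0(side, "_wrist"), "arm", side, NA_character_, NA_integer_,
      paste0(side, "_elbow"), wr, c(0, -1, 0), forearm)
    # hand root: its own root joint, co-located with the wrist at rest
    add(paste0(side, "_hand_root"), "hand", side, NA_character_, NA_integer_,
      NA_character_, wr, c(NA_real_, NA_real_, NA_real_), NA_real_)
    for (dg in digits) {
      lat <- -sgn * lat_left[[dg]] * hand_scale # mirror-symmetric about x = 0
      base_vec <- c(lat, -base_drop, 0)
      base_len <- v_norm(base_vec)
      base_dir <- base_vec / base_len
      p <- wr + base_vec
      add(paste(side, dg, 1, sep = "_"), "hand", side, dg, 1L,
        paste0(side, "_hand_root"), p, base_dir, base_len)
      seg_dir <- v_unit(c(lat * 0.4, -1, 0))
      parent <- paste(side, dg, 1, sep = "_")
      for (k in 2:4) {
        len <- phal[k - 1] * seg_mult[[dg]]
        p <- p + seg_dir * len
        add(paste(side, dg, k, sep = "_"), "hand", side, dg, as.integer(k),
          parent, p, seg_dir, len)
        parent <- paste(side, dg, k, sep = "_")
      }
    }
  }
  skel <- bind_rows(rows)
  attr(skel, "skeleton_name") <- name
  class(skel) <- c("skeleton", class(skel))
  skel
}

#' Shipped default skeletons
#'
#' `"adult_user"` is a schematic adult subject seated about 1.6 m from the
#' camera plane; `"avatar"` is the virtual body the motion is retargeted to,
#' with arm segments 15% longer than the user's so that retargeting exercises
#' non-unit limb scaling.
#'
#' @param name `"adult_user"` or `"avatar"`.
#' @return A `"skeleton"` tibble, see [skeleton_build()].
#' @export
skeleton_default <- function(name = c("adult_user", "avatar")) {
  name <- match.arg(name)
  switch(name,
    adult_user = skeleton_build("adult_user"),
    avatar = skeleton_build("avatar",
      upper_arm = 0.345, forearm = 0.322, hand_scale = 1.15
    )
  )
}

#' Read or write a skeleton definition as JSON
#'
#' The on-disk format is a JSON document with the skeleton name and one record
#' per joint (identity, topology, rest geometry). Copies of the two default
#' skeletons ship under `system.file("extdata", "skeletons", package =
#' "rehabtrack")`.
#'
#' @param path File path.
#' @param skel A `"skeleton"` tibble.
#' @return `skeleton_read()` returns a `"skeleton"` tibble;
#'   `skeleton_write()` returns `path` invisibly.
#' @export
skeleton_read <- function(path) {
  doc <- jsonlite::fromJSON(path)
  skel <- as_tibble(doc$joints)
  skel$chain_index <- as.integer(skel$chain_index)
  attr(skel, "skeleton_name") <- doc$name
  class(skel) <- c("skeleton", class(skel))
  validate_skeleton(skel)
  skel
}

#' @rdname skeleton_read
#' @export
skeleton_write <- function(skel, path) {
  doc <- list(
    name = attr(skel, "skeleton_name") %||% "skeleton",
    joints = as.data.frame(skel)
  )
  jsonlite::write_json(doc, path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null"
  )
  invisible(path)
}

# internal structural checks: unique ids, 6/42 split, acyclic parent map,
# arm chains, positive lengths, unit rest directions
validate_skeleton <- function(skel) {
  jt <- joint_table()
  if (!setequal(skel$joint, jt$joint) || anyDuplicated(skel$joint) > 0) {
    abort("skeleton must define each of the 48 upper-limb joints exactly once",
      class = "rehabtrack_invalid_skeleton"
    )
  }
  kids <- skel$joint[!is.na(skel$parent)]
  if (!all(skel$parent[!is.na(skel$parent)] %in% skel$joint)) {
    abort("skeleton parent map references unknown joints",
      class = "rehabtrack_invalid_skeleton"
    )
  }
  if (any(skel$length[skel$joint %in% kids] <= 0, na.rm = FALSE)) {
    abort("all bone lengths must be positive", class = "rehabtrack_invalid_skeleton")
  }
  dirs <- as.matrix(skel[skel$joint %in% kids, c("dir_x", "dir_y", "dir_z")])
  if (any(abs(sqrt(rowSums(dirs^2)) - 1) > 1e-9)) {
    abort("rest bone directions must be unit vectors", class = "rehabtrack_invalid_skeleton")
  }
  invisible(skel)
}

#' @export
print.skeleton <- function(x, ...) {
  cat(
    "<skeleton>", attr(x, "skeleton_name") %||% "", "-",
    nrow(x), "joints (6 arm / 42 hand)\n"
  )
  NextMethod()
}

# arm segment lengths c(upper, fore) for one side
arm_lengths <- function(skel, side) {
  c(
    skel$length[skel$joint == paste0(side, "_elbow")],
    skel$length[skel$joint == paste0(side, "_wrist")]
  )
}

# named n x 3 matrix of rest positions
rest_positions <- function(skel) {
  m <- as.matrix(skel[, c("rest_x", "rest_y", "rest_z")])
  dimnames(m) <- list(skel$joint, NULL)
  m
}

#' Rest pose of a skeleton as a pose frame
#'
#' @param skel A `"skeleton"` tibble.
#' @param time Timestamp (s) stamped on the frame.
#' @return A pose tibble with columns `time`, `joint`, `x`, `y`, `z`, `conf`.
#' @export
skeleton_rest_pose <- function(skel, time = 0) {
  tibble(
    time = time, joint = skel$joint,
    x = skel$rest_x, y = skel$rest_y, z = skel$rest_z, conf = 1
  )
}

#' Validate a 3D pose frame against a skeleton
#'
#' Validation never throws: it returns a report tibble with one row per
#' violated invariant (missing or duplicated joints, confidences outside
#' \[0, 1\], non-finite positions carrying positive confidence, invalid
#' timestamps, and bone lengths deviating from the skeleton's rest length by
#' more than `tol_bone` relative). An empty report means the frame is
#' consistent. Bone lengths are only checked between joints that are both
#' observed with positive confidence.
#'
#' @param frame A single-timestamp pose tibble (`time`, `joint`, `x`, `y`,
#'   `z`, `conf`).
#' @param skel The `"skeleton"` the frame is measured on.
#' @param tol_bone Relative bone-length tolerance (default 10%).
#' @return A tibble with columns `check`, `joint`, `detail`; zero rows iff
#'   the frame is consistent.
#' @examples
#' skel <- skeleton_default("adult_user")
#' validate_frame(skeleton_rest_pose(skel), skel) # zero rows
#' @export
validate_frame <- function(frame, skel, tol_bone = 0.1) {
  out <- list()
  bad <- function(check, joint, detail) {
    out[[length(out) + 1]] <<- tibble(check = check, joint = joint, detail = detail)
  }
  if (length(unique(frame$time)) > 1) {
    bad("multiple_timestamps", NA_character_, "frame spans more than one timestamp")
  }
  for (j in setdiff(skel$joint, frame$joint)) bad("missing_joint", j, "joint absent from frame")
  for (j in unique(frame$joint[duplicated(frame$joint)])) {
    bad("duplicate_joint", j, "joint appears more than once")
  }
  if (any(!is.finite(frame$time) | frame$time < 0)) {
    bad("timestamp", NA_character_, "timestamp must be finite and non-negative")
  }
  oob <- !is.finite(frame$conf) | frame$conf < 0 | frame$conf > 1
  for (j in frame$joint[oob]) bad("confidence_range", j, "confidence outside [0, 1]")
  nf <- frame$conf > 0 & !(is.finite(frame$x) & is.finite(frame$y) & is.finite(frame$z))
  nf[is.na(nf)] <- FALSE
  for (j in frame$joint[nf]) bad("nonfinite_position", j, "non-finite position with positive confidence")

  idx <- match(frame$joint, frame$joint) # first occurrence lookup
  pos <- function(j) {
    i <- match(j, frame$joint)
    if (is.na(i)) NULL else c(frame$x[i], frame$y[i], frame$z[i])
  }
  cf <- function(j) {
    i <- match(j, frame$joint)
    if (is.na(i)) 0 else frame$conf[i]
  }
  bones <- skel[!is.na(skel$parent), ]
  for (i in seq_len(nrow(bones))) {
    child <- bones$joint[i]
    parent <- bones$parent[i]
    pc <- pos(child)
    pp <- pos(parent)
    if (is.null(pc) || is.null(pp)) next
    if (cf(child) <= 0 || cf(parent) <= 0) next
    if (!all(is.finite(c(pc, pp)))) next
    len <- v_norm(pc - pp)
    rest <- bones$length[i]
    if (abs(len - rest) / rest > tol_bone) {
      bad(
        "bone_length", child,
        sprintf("%s->%s length %.4f m vs rest %.4f m", parent, child, len, rest)
      )
    }
  }
  if (length(out) == 0) {
    tibble(check = character(), joint = character(), detail = character())
  } else {
    bind_rows(out)
  }
}

#' Mirror a pose frame across a sagittal plane
#'
#' Reflects every joint position across the plane and swaps the left/right
#' labels, so a left-limb movement drives the contralateral (right) limb —
#' the mapping used by the mirrored-motion therapy tasks. Confidences and the
#' timestamp are carried over unchanged. The default plane is the world
#' midline `x = 0`, which is also the symmetry plane of the shipped
#' skeletons. Mirroring is an involution and an isometry.
#'
#' @param frame A pose tibble (`time`, `joint`, `x`, `y`, `z`, `conf`); may
#'   contain several timestamps, all are mirrored.
#' @param point A point on the mirror plane.
#' @param normal Plane normal; must have non-zero norm (it is normalised).
#' @return The mirrored pose tibble (same rows, relabelled joints).
#' @export
mirror_pose <- function(frame, point = c(0, 0, 0), normal = c(1, 0, 0)) {
  if (!is.numeric(normal) || length(normal) != 3 || v_norm(normal) < 1e-12) {
    abort("mirror plane normal must be a non-zero 3-vector",
      class = "rehabtrack_invalid_argument"
    )
  }
  normal <- normal / v_norm(normal)
  p <- as.matrix(frame[, c("x", "y", "z")])
  p <- reflect_points(p, point, normal)
  swapped <- frame$joint
  swapped <- ifelse(startsWith(swapped, "left_"),
    sub("^left_", "right_", swapped),
    sub("^right_", "left_", swapped)
  )
  out <- frame
  out$joint <- swapped
  out$x <- unname(p[, 1])
  out$y <- unname(p[, 2])
  out$z <- unname(p[, 3])
  out
}
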