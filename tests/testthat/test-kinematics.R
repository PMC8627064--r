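test_that("bone_orientation returns the minimal rotation", {
  # measured equals rest: identity
  q <- bone_orientation(c(0, 0, 0), c(1, 0, 0), c(1, 0, 0))
  expect_equal(q, c(1, 0, 0, 0), tolerance = 1e-12)
  # 90 degrees about z carries +x onto +y
  q <- bone_orientation(c(0, 0, 0), c(0, 2, 0), c(1, 0, 0))
  expect_equal(q, c(cos(pi / 4), 0, 0, sin(pi / 4)), tolerance = 1e-12)
  # antipodal: half turn about the fallback axis, deterministic
  q1 <- bone_orientation(c(0, 0, 0), c(-1, 0, 0), c(1, 0, 0))
  q2 <- bone_orientation(c(0, 0, 0), c(-3, 0, 0), c(1, 0, 0))
  expect_equal(q1, q2)
  expect_equal(abs(sum(q1 * q1)), 1, tolerance = 1e-12)
  expect_equal(q1[1], 0, tolerance = 1e-12) # pure half turn
  expect_error(
    bone_orientation(c(1, 1, 1), c(1, 1, 1), c(1, 0, 0)),
    class = "rehabtrack_zero_length_bone"
  )
})

test_that("finger FK with identity orientations reproduces the rest pose", {
  bones <- user_skel[user_skel$category == "hand" & user_skel$side == "left" &
    !is.na(user_skel$parent), ]
  idq <- tibble::tibble(joint = bones$joint, qw = 1, qx = 0, qy = 0, qz = 0)
  root <- c(0.5, 1.0, 0.2)
  fk <- finger_fk(idq, user_skel, root, "left")
  rest <- rest_positions(user_skel)
  shift <- root - rest["left_hand_root", ]
  for (j in fk$joint) {
    expect_equal(
      c(fk$x[fk$joint == j], fk$y[fk$joint == j], fk$z[fk$joint == j]),
      rest[j, ] + shift,
      tolerance = 1e-12
    )
  }
  expect_error(
    finger_fk(idq[-1, ], user_skel, root, "left"),
    class = "rehabtrack_incomplete_pose"
  )
})

test_that("uniform 90-degree flexion matches a brute-force chain oracle", {
  # synthetic 4-bone chain with equal lengths: replace the index chain
  skel <- user_skel
  idx <- which(skel$side == "left" & !is.na(skel$digit) & skel$digit == "index")
  L <- 0.03
  skel$length[idx] <- L
  skel$dir_x[idx] <- 1
  skel$dir_y[idx] <- 0
  skel$dir_z[idx] <- 0

  bones <- skel[skel$category == "hand" & skel$side == "left" &
    !is.na(skel$parent), ]
  q90 <- quat_axis_angle(c(0, 0, 1), pi / 2)
  orients <- tibble::tibble(
    joint = bones$joint,
    qw = ifelse(bones$digit == "index", q90[1], 1),
    qx = 0, qy = 0,
    qz = ifelse(bones$digit == "index", q90[4], 0)
  )
  fk <- finger_fk(orients, skel, c(0, 0, 0), "left")

  # independent accumulation: directions rotate 90 deg more at each joint
  p <- c(0, 0, 0)
  expected <- list()
  dirs <- list(c(0, 1, 0), c(-1, 0, 0), c(0, -1, 0), c(1, 0, 0))
  for (k in 1:4) {
    p <- p + dirs[[k]] * L
    expected[[k]] <- p
  }
  for (k in 1:4) {
    jn <- paste0("left_index_", k)
    expect_equal(
      c(fk$x[fk$joint == jn], fk$y[fk$joint == jn], fk$z[fk$joint == jn]),
      expected[[k]],
      tolerance = 1e-12
    )
  }
})

test_that("measured hand orientations round-trip through finger FK", {
  fr <- random_valid_frame(3)
  for (side in c("left", "right")) {
    orients <- hand_orientations(fr, user_skel, side)
    root <- pos_of(fr, paste0(side, "_hand_root"))
    fk <- finger_fk(orients, user_skel, root, side)
    for (j in fk$joint) {
      expect_equal(
        c(fk$x[fk$joint == j], fk$y[fk$joint == j], fk$z[fk$joint == j]),
        pos_of(fr, j),
        tolerance = 1e-6
      )
    }
  }
})

test_that("arm IK solves the law of cosines", {
  s <- arm_ik(c(0, 0, 0), c(0.3, 0, 0), c(0.15, -0.2, 0), L1 = 0.3, L2 = 0.3)
  expect_equal(s$elbow_angle, pi / 3, tolerance = 1e-12) # 60 degrees
  expect_true(s$reachable)
  # full extension: interior angle pi, elbow on the segment
  s2 <- arm_ik(c(0, 0, 0), c(0.58, 0, 0), c(0.2, -0.1, 0), L1 = 0.30, L2 = 0.28)
  expect_equal(s2$elbow_angle, pi, tolerance = 1e-6)
  expect_equal(s2$elbow_pos, c(0.30, 0, 0), tolerance = 1e-9)
})

test_that("FK of the IK solution reproduces 1000 random reachable targets", {
  set.seed(1234)
  worst <- 0
  for (i in 1:1000) {
    L1 <- runif(1, 0.2, 0.4)
    L2 <- runif(1, 0.2, 0.4)
    d <- runif(1, abs(L1 - L2) + 1e-6, L1 + L2 - 1e-6)
    dir <- v_unit(rnorm(3))
    sh <- rnorm(3)
    target <- sh + d * dir
    hint <- sh + rnorm(3) * 0.2
    s <- arm_ik(sh, target, hint, L1, L2)
    expect_true(s$reachable)
    # forward kinematics: shoulder -> elbow -> wrist with the solved geometry
    expect_equal(v_norm(s$elbow_pos - sh), L1, tolerance = 1e-9)
    expect_equal(v_norm(s$wrist_pos - s$elbow_pos), L2, tolerance = 1e-9)
    worst <- max(worst, v_norm(s$wrist_pos - target))
  }
  expect_lt(worst, 1e-9)
})

test_that("unreachable targets are clamped to the annulus, not rejected", {
  s <- arm_ik(c(0, 0, 0), c(1, 0, 0), c(0.3, -0.2, 0), L1 = 0.3, L2 = 0.28)
  expect_false(s$reachable)
  expect_equal(s$target_clamped, c(0.58, 0, 0), tolerance = 1e-12)
  s2 <- arm_ik(c(0, 0, 0), c(0.005, 0, 0), c(0.1, -0.2, 0), L1 = 0.3, L2 = 0.28)
  expect_false(s2$reachable)
  expect_equal(v_norm(s2$target_clamped), 0.02, tolerance = 1e-12)
})

test_that("elbow flexion decreases continuously with target distance", {
  L1 <- 0.31
  L2 <- 0.27
  ds <- seq(abs(L1 - L2) + 1e-4, L1 + L2 - 1e-4, length.out = 400)
  flex <- vapply(ds, function(d) {
    arm_ik(c(0, 0, 0), c(d, 0, 0), c(d / 2, -0.1, 0), L1, L2)$flexion
  }, numeric(1))
  expect_true(all(diff(flex) < 0)) # flexion decreases (interior angle grows)
  expect_lt(max(abs(diff(flex))), 0.2) # no jumps on the dense grid
})

test_that("degenerate swivel hints fall back deterministically", {
  # hint exactly on the shoulder-target axis
  s <- arm_ik(c(0, 0, 0), c(0.4, 0, 0), c(0.2, 0, 0), L1 = 0.3, L2 = 0.28)
  expect_equal(sum(s$swivel * c(1, 0, 0)), 0, tolerance = 1e-12)
  expect_equal(s$swivel, c(0, -1, 0), tolerance = 1e-12) # elbow-down default
  # previous-frame swivel wins over the default
  s2 <- arm_ik(c(0, 0, 0), c(0.4, 0, 0), c(0.2, 0, 0),
    L1 = 0.3, L2 = 0.28,
    prev_swivel = c(0, 0, 1)
  )
  expect_equal(s2$swivel, c(0, 0, 1), tolerance = 1e-12)
})

test_that("retargeting between identical skeletons is the identity on wrists", {
  fr <- random_valid_frame(11)
  ap <- retarget(fr, user_skel, user_skel, mode = "normal")
  for (j in c("left_wrist", "right_wrist", "left_elbow")) {
    expect_equal(
      as.numeric(ap$positions[ap$positions$joint == j, c("x", "y", "z")]),
      pos_of(fr, j),
      tolerance = 1e-6
    )
  }
})

test_that("a longer avatar arm scales wrist displacement by the length ratio", {
  skel2x <- skeleton_build("double", upper_arm = 0.60, forearm = 0.56)
  fr <- skeleton_rest_pose(user_skel)
  # move the left wrist to a bent-arm position
  tgt <- c(-0.10, 1.10, 1.45)
  i <- match("left_wrist", fr$joint)
  fr$x[i] <- tgt[1]
  fr$y[i] <- tgt[2]
  fr$z[i] <- tgt[3]
  el <- c(-0.25, 1.1, 1.65) # consistent-enough elbow hint
  j <- match("left_elbow", fr$joint)
  fr$x[j] <- el[1]
  fr$y[j] <- el[2]
  fr$z[j] <- el[3]
  # keep the hand joints rigidly attached to the wrist for a parseable frame
  shift <- tgt - rest_positions(user_skel)["left_wrist", ]
  hand <- user_skel$joint[user_skel$category == "hand" & user_skel$side == "left"]
  k <- fr$joint %in% hand
  fr$x[k] <- fr$x[k] + shift[1]
  fr$y[k] <- fr$y[k] + shift[2]
  fr$z[k] <- fr$z[k] + shift[3]

  ap <- retarget(fr, user_skel, skel2x, mode = "normal")
  sh_u <- pos_of(fr, "left_shoulder")
  sh_a <- rest_positions(skel2x)["left_shoulder", ]
  wr_a <- as.numeric(ap$positions[ap$positions$joint == "left_wrist", c("x", "y", "z")])
  expect_equal(wr_a - sh_a, 2 * (tgt - sh_u), tolerance = 1e-9)
})

test_that("retargeting preserves avatar bone lengths", {
  fr <- random_valid_frame(21)
  ap <- retarget(fr, user_skel, avatar_skel, mode = "normal")
  pose <- dplyr::mutate(ap$positions, time = 0, conf = 1)
  report <- validate_frame(pose, avatar_skel, tol_bone = 1e-9)
  expect_equal(nrow(report), 0)
})

test_that("mirrored retargeting equals retargeting the mirrored frame", {
  fr <- random_valid_frame(31)
  a <- retarget(fr, user_skel, avatar_skel, mode = "mirrored")
  b <- retarget(mirror_pose(fr), user_skel, avatar_skel, mode = "normal")
  expect_equal(a$positions, b$positions, tolerance = 1e-12)
})

test_that("mirrored mode drives only the contralateral avatar arm", {
  sc <- reach_script(duration = 0.5, fps = 10) # left arm moves
  gm <- generate_motion(sc, user_skel)
  out <- retarget_stream(gm, user_skel, avatar_skel, mode = "mirrored")
  spread <- out %>%
    dplyr::group_by(joint) %>%
    dplyr::summarise(s = max(x) - min(x) + max(y) - min(y) + max(z) - min(z))
  right_arm <- spread$s[spread$joint %in% c("right_elbow", "right_wrist")]
  left_arm <- spread$s[spread$joint %in% c("left_elbow", "left_wrist")]
  expect_true(all(right_arm > 0.01)) # avatar right arm follows
  expect_true(all(left_arm < 1e-9)) # avatar left arm static
})

test_that("grasp closure thresholds mean digit flexion", {
  open_fr <- skeleton_rest_pose(user_skel) # naturally stretched hand
  sc <- motion_script("grasp",
    start = c(-0.05, 1.30, 1.58), target = c(0.1, 1.30, 1.45),
    duration = 1, fps = 4, side = "left"
  )
  closed_fr <- frame_at(generate_motion(sc, user_skel), 1)
  expect_false(grasp_closed(open_fr, user_skel, "left"))
  expect_true(grasp_closed(closed_fr, user_skel, "left"))
})
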