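test_that("project-then-triangulate recovers the point", {
  p <- c(0.07, 1.22, 1.48)
  oa <- as.numeric(as.matrix(project_points(rig$a, rbind(p))))
  ob <- as.numeric(as.matrix(project_points(rig$b, rbind(p))))
  tri <- triangulate(oa, rig$a, ob, rig$b)
  expect_lt(sqrt(sum((tri$point - p)^2)), 1e-9)
  expect_lt(tri$residual, 1e-9)
})

test_that("rays constructed to intersect give zero residual at the crossing", {
  # both optical axes pass through the look-at point of the default rig
  target <- c(0, 1.2, 1.6)
  oa <- c(rig$a$cx, rig$a$cy)
  ob <- c(rig$b$cx, rig$b$cy)
  tri <- triangulate(oa, rig$a, ob, rig$b)
  expect_equal(tri$point, target, tolerance = 1e-9)
  expect_lt(tri$residual, 1e-9)
})

test_that("degenerate two-view geometry is rejected", {
  cam1 <- camera_model(1000, 1000, 500, 500, 1000, 1000, diag(3), c(0, 0, 0), "c1")
  cam2 <- camera_model(1000, 1000, 500, 500, 1000, 1000, diag(3), c(0, 0, 0), "c2")
  expect_error(
    triangulate(c(500, 500), cam1, c(500, 500), cam2),
    class = "rehabtrack_degenerate_geometry"
  )
  # distinct centers but parallel rays
  cam3 <- camera_model(1000, 1000, 500, 500, 1000, 1000, diag(3), c(-0.5, 0, 0), "c3")
  expect_error(
    triangulate(c(500, 500), cam1, c(500, 500), cam3),
    class = "rehabtrack_degenerate_geometry"
  )
})

test_that("fusion applies the min-confidence and dropout rules", {
  fr <- skeleton_rest_pose(user_skel)
  kp <- render_keypoints(fr, rig, sigma = 0, dropout = 0)
  # drop the left wrist in camera A only
  i <- which(kp$camera == "cam_a" & kp$joint == "left_wrist")
  kp$conf[i] <- 0
  kp$u[i] <- NA
  # lower right elbow confidence in camera B
  j <- which(kp$camera == "cam_b" & kp$joint == "right_elbow")
  kp$conf[j] <- 0.4
  fused <- fuse_streams(kp, rig)
  expect_equal(fused$conf[fused$joint == "left_wrist"], 0)
  expect_true(is.na(fused$x[fused$joint == "left_wrist"]))
  expect_equal(fused$conf[fused$joint == "right_elbow"], 0.4)

  # all joints dropped in both cameras -> all-zero confidences
  kp0 <- kp
  kp0$conf <- 0
  fused0 <- fuse_streams(kp0, rig)
  expect_true(all(fused0$conf == 0))

  # camera ids must match the rig
  kp_bad <- kp
  kp_bad$camera[kp_bad$camera == "cam_a"] <- "other"
  expect_error(fuse_streams(kp_bad, rig), class = "rehabtrack_invalid_argument")
})

test_that("noise-free two-camera round trip reproduces ground truth", {
  sc <- reach_script(duration = 1, fps = 30, amplitude = 0.02)
  gm <- generate_motion(sc, user_skel)
  kp <- render_keypoints(gm, rig, sigma = 0, dropout = 0)
  p3 <- filter_stream(fuse_streams(kp, rig), filter_params("none"))
  j <- dplyr::inner_join(gm, p3, by = c("time", "joint"), suffix = c("", ".r"))
  expect_equal(nrow(j), nrow(gm))
  expect_lt(max(abs(j$x - j$x.r), abs(j$y - j$y.r), abs(j$z - j$z.r)), 1e-6)
})

test_that("filters preserve constant streams and 'none' is the identity", {
  fr <- dplyr::bind_rows(lapply(0:20 / 30, function(t) {
    dplyr::mutate(skeleton_rest_pose(user_skel), time = t)
  }))
  for (kind in c("one_euro", "ema", "none")) {
    out <- filter_stream(fr, filter_params(kind))
    expect_equal(out$x, fr$x, tolerance = 1e-12)
    expect_equal(out$y, fr$y, tolerance = 1e-12)
    expect_equal(nrow(out), nrow(fr))
  }
  bad <- fr
  bad$time <- rev(bad$time)
  expect_error(filter_stream(bad, filter_params()), class = "rehabtrack_invalid_argument")
})

test_that("step response is monotone and converges to the new level", {
  n <- 200
  fr <- tibble::tibble(
    time = (0:(n - 1)) / 30, joint = "left_wrist",
    x = c(rep(0, 20), rep(1, n - 20)), y = 0, z = 0, conf = 1
  )
  out <- filter_stream(fr, filter_params("one_euro"))
  xs <- out$x[20:n]
  expect_true(all(diff(xs) >= -1e-12)) # monotone between the levels
  expect_true(all(xs <= 1 + 1e-12))
  expect_gt(max(out$x), 0.99) # reaches within 1% of the new level
})

test_that("gap-filled joints hold the last value with decaying confidence", {
  fr <- tibble::tibble(
    time = (0:9) / 30, joint = "left_wrist",
    x = sin(0:9), y = 0, z = 0,
    conf = c(1, 1, 1, 0, 0, 1, 1, 1, 1, 1)
  )
  out <- filter_stream(fr, filter_params("one_euro"))
  expect_equal(out$x[4], out$x[3]) # held
  expect_equal(out$conf[4], 0.9)
  expect_equal(out$conf[5], 0.81)
  expect_true(all(is.finite(out$x)))
})

test_that("One-Euro filtering does not hurt accuracy under pixel noise", {
  rmse <- function(a, b) sqrt(mean((a$x - b$x)^2 + (a$y - b$y)^2 + (a$z - b$z)^2))
  worse <- 0
  gains <- c()
  for (seed in 1:10) {
    sc <- reach_script(duration = 1.5, fps = 30)
    gm <- generate_motion(sc, user_skel)
    kp <- render_keypoints(gm, rig, sigma = 2, dropout = 0, seed = seed)
    raw <- fuse_streams(kp, rig)
    raw <- dplyr::arrange(raw, time, joint)
    flt <- dplyr::arrange(filter_stream(raw, filter_params("one_euro")), time, joint)
    gt <- dplyr::arrange(gm, time, joint)
    e_raw <- rmse(raw, gt)
    e_flt <- rmse(flt, gt)
    gains <- c(gains, e_raw - e_flt)
    if (e_flt > e_raw * 1.05) worse <- worse + 1
  }
  expect_equal(worse, 0) # never worse than 5% over NONE
  expect_gt(mean(gains), 0) # better on average
})
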