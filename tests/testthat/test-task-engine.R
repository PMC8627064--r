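test_that("task configuration validates its invariants", {
  expect_error(task_config(trials = 0), class = "rehabtrack_invalid_argument")
  expect_error(task_config(limb_switch = 31), class = "rehabtrack_invalid_argument")
  expect_error(task_config(hold = 0), class = "rehabtrack_invalid_argument")
})

test_that("targets spawn uniformly over the reach area", {
  cfg <- task_config(seed = 2)
  set.seed(cfg$seed)
  sp <- spawn_targets(cfg, 10000)
  ctr <- cfg$reach_area$center
  ext <- cfg$reach_area$extent
  expect_lt(abs(mean(sp$x) - ctr[1]), 0.02)
  expect_lt(abs(mean(sp$z) - ctr[3]), 0.02)
  expect_true(all(sp$y == ctr[2])) # constant height
  expect_true(all(abs(sp$x - ctr[1]) <= ext[1] / 2))
  expect_true(all(abs(sp$z - ctr[3]) <= ext[2] / 2))

  set.seed(99)
  a <- spawn_targets(cfg, 50)
  set.seed(99)
  b <- spawn_targets(cfg, 50)
  expect_identical(a, b)

  bad <- cfg
  bad$reach_area$extent <- c(0, 0.3)
  expect_error(spawn_targets(bad, 1), class = "rehabtrack_invalid_argument")
})

test_that("a never-reaching hand times out at exactly the reach timeout", {
  cfg <- task_config(trials = 1, limb_switch = 1, seed = 5)
  s <- simulate_session(cfg, policy_hold_start())
  ev <- s$events
  unf <- ev[ev$event == "trial_unfinished", ]
  expect_equal(nrow(unf), 1)
  expect_equal(unf$value, 4.0, tolerance = 1e-9)
  expect_equal(s$trials$outcome, "unfinished")
  expect_equal(s$trials$score, 0)
  expect_true(is.na(s$trials$reach_time))
})

test_that("start hold completes after exactly the hold duration", {
  cfg <- task_config(trials = 1, limb_switch = 1, seed = 5)
  s <- simulate_session(cfg, policy_hold_start())
  green <- s$events[s$events$event == "start_area_green", ]
  expect_equal(green$value[1], 1.5, tolerance = 1e-9)
  expect_equal(green$time[1], 1.5, tolerance = 1e-9)
})

test_that("time regression is rejected by the state machine", {
  cfg <- small_cfg()
  st <- trial_step(NULL, cfg$start_center, FALSE, 1.0, cfg)$state
  expect_error(
    trial_step(st, cfg$start_center, FALSE, 0.5, cfg),
    class = "rehabtrack_invalid_argument"
  )
})

test_that("a full default session yields 30 trials switching limb after 15", {
  cfg <- task_config(seed = 31)
  s <- simulate_session(cfg, policy_line_follower())
  expect_equal(nrow(s$trials), 30)
  expect_equal(s$trials$limb, rep(c("left", "right"), each = 15))
  expect_true(all(s$trials$outcome == "finished"))
  expect_true(all(s$trials$reach_time <= cfg$timeout))
})

test_that("scaled-down configurations assign limbs by the switch index", {
  s <- simulate_session(small_cfg(), policy_line_follower())
  expect_equal(s$trials$limb, c("left", "left", "right", "right"))
  m <- simulate_session(small_cfg(kind = "mirrored"), policy_line_follower())
  expect_equal(m$trials$avatar_limb, c("right", "right", "left", "left"))
})

test_that("an exhausted trace raises a truncated-session error with records", {
  cfg <- small_cfg()
  full <- simulate_session(cfg, policy_line_follower())
  # rebuild the trace and cut it just before trial 3's target spawns
  trace <- dplyr::bind_rows(full$trials$trace)
  cut_t <- full$trials$spawn_time[3] - 0.1
  err <- tryCatch(
    run_session(trace[trace$time <= cut_t, ], cfg),
    error = function(e) e
  )
  expect_s3_class(err, "rehabtrack_truncated_session")
  expect_equal(err$trials_completed, 2)
  expect_equal(nrow(err$records), 2)
})

test_that("run_session on a recorded trace reproduces the simulated session", {
  cfg <- small_cfg()
  sim <- simulate_session(cfg, policy_line_follower())
  trace <- dplyr::bind_rows(sim$trials$trace)
  rerun <- run_session(trace, cfg)
  expect_equal(rerun$trials$outcome, sim$trials$outcome)
  expect_equal(rerun$trials$score, sim$trials$score)
  expect_equal(rerun$trials$spawn_time, sim$trials$spawn_time)
})

test_that("sessions are bit-identical under a fixed seed", {
  a <- simulate_session(small_cfg(), policy_line_follower())
  b <- simulate_session(small_cfg(), policy_line_follower())
  expect_identical(a$trials, b$trials)
  expect_identical(a$events, b$events)
  c <- simulate_session(small_cfg(seed = 8), policy_line_follower())
  expect_false(identical(a$trials, c$trials))
})

test_that("color cues follow the scripted order on the success path", {
  s <- simulate_session(small_cfg(trials = 1L, limb_switch = 1L), policy_line_follower())
  ev <- s$events$event
  ord <- match(
    c("trial_start", "start_area_green", "start_area_gray", "object_spawn",
      "object_green", "trial_finished", "start_area_blue"),
    ev
  )
  expect_false(any(is.na(ord)))
  expect_true(all(diff(ord) > 0))
})

test_that("a hold that completes after the 4 s mark still finishes the trial", {
  # enter the object at 3.9 s of reaching, leave briefly, re-enter, hold:
  # reached-within-timeout is judged on first entry only
  cfg <- task_config(trials = 1, limb_switch = 1, seed = 13)
  set.seed(cfg$seed)
  obj <- as.numeric(spawn_targets(cfg, 1)) # same first spawn as the session
  far <- obj + c(0, 0, 0.1)
  dt <- 1 / cfg$fps
  mk <- function(t0, t1, pos) {
    tt <- seq(t0, t1 - dt / 2, by = dt)
    tibble::tibble(time = tt, x = pos[1], y = pos[2], z = pos[3])
  }
  trace <- dplyr::bind_rows(
    mk(0, 1.5 + dt, cfg$start_center), # hold; spawn fires at ~1.5 s
    mk(1.5 + dt, 5.4, far), # reaching, not near
    mk(5.4, 5.6, obj), # first entry at ~3.9 s elapsed
    mk(5.6, 5.8, far), # leaves before the hold completes
    mk(5.8, 7.6, obj), # re-enter and hold 1.5 s
    mk(7.6, 9.0, cfg$start_center) # return
  )
  s <- run_session(trace, cfg)
  expect_equal(s$trials$outcome, "finished")
  expect_lt(s$trials$reach_time, cfg$timeout)
})

test_that("grasp trials require closure on object 1 then score along the line", {
  cfg <- small_cfg(kind = "grasp", trials = 2L, limb_switch = 1L)
  s <- simulate_session(cfg, policy_line_follower())
  expect_equal(s$trials$outcome, rep("finished", 2))
  ev <- s$events$event[s$events$trial == 1]
  expect_true("object_yellow" %in% ev)
  expect_equal(sum(ev == "object_spawn"), 2) # object 1 then object 2
  # the guide line ends at object 2 (the recorded target) and both line
  # endpoints share the reach space's constant height
  expect_equal(
    s$trials$line[[1]][2, ], s$trials$object[[1]],
    tolerance = 1e-9, ignore_attr = TRUE
  )
  expect_equal(s$trials$line[[1]][1, 2], s$trials$line[[1]][2, 2])
  # a hand that never closes (nor approaches) times out on object 1
  s2 <- simulate_session(
    small_cfg(kind = "grasp", trials = 1L, limb_switch = 1L),
    policy_hold_start()
  )
  expect_equal(s2$trials$outcome, "unfinished")
})

test_that("every trial ends finished xor unfinished within the timeout rule", {
  for (kind in c("normal", "grasp")) {
    s <- simulate_session(small_cfg(kind = kind), policy_line_follower())
    expect_true(all(s$trials$outcome %in% c("finished", "unfinished")))
    fin <- s$trials$outcome == "finished"
    expect_true(all(s$trials$reach_time[fin] <= s$config$timeout))
    expect_true(all(is.na(s$trials$reach_time[!fin])))
  }
})
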