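#' Configuration of one rehabilitation task session
#'
#' Encodes the trial paradigm shared by the three task kinds. A session is a
#' fixed number of trials (default 30); the first `limb_switch` trials
#' (default 15) use the left upper limb, the remainder the right. Each trial:
#' hold the hand in the start area for `hold` seconds (the area turns from
#' blue to green), a target object spawns uniformly at random in the
#' calibrated reach area with a guide line (start area turns gray), the
#' object must be reached -- and for `"grasp"` trials, grasped -- within
#' `timeout` seconds and held for `hold` seconds, then the score is shown for
#' `score_display` seconds and the hand returns to the start area (which
#' turns blue again) before the next trial. Grasp trials first require
#' grasping object 1 and holding it, after which object 2 spawns with a
#' guide line anchored at object 1.
#'
#' @param kind `"normal"`, `"mirrored"` or `"grasp"`.
#' @param trials Trials per session, > 0.
#' @param hold Continuous hold duration (s) for start area and target.
#' @param timeout Maximum reaching time (s) before a trial counts as
#'   unfinished.
#' @param score_display How long the per-trial score stays on screen (s).
#' @param limb_switch Number of leading trials assigned to the left limb.
#' @param fps Frame rate (Hz) used by [simulate_session()].
#' @param reach_area Per-subject calibrated spawn region: a list with
#'   `center` (3-vector, m) and `extent` (x and z widths, m) of a horizontal
#'   rectangle at the center's height. For grasp trials this is the reach
#'   space at its constant height.
#' @param start_center,start_radius Start area center (m) and radius (m).
#' @param object_radius Proximity radius (m) within which the hand counts as
#'   at the object ("an object of a constant size").
#' @param grasp_threshold Mean digit flexion (rad) above which the hand
#'   counts as closed.
#' @param seed Integer seed driving target placement.
#' @return A list of class `"task_config"`.
#' @export
task_config <- function(kind = c("normal", "mirrored", "grasp"),
                        trials = 30L, hold = 1.5, timeout = 4.0,
                        score_display = 1.0, limb_switch = 15L, fps = 30,
                        reach_area = list(
                          center = c(0, 1.30, 1.45),
                          extent = c(0.5, 0.3)
                        ),
                        start_center = c(0, 1.30, 1.60), start_radius = 0.06,
                        object_radius = 0.04, grasp_threshold = pi / 3,
                        seed = 1L) {
  kind <- match.arg(kind)
  trials <- as.integer(trials)
  limb_switch <- as.integer(limb_switch)
  if (trials <= 0 || limb_switch <= 0 || limb_switch > trials ||
    hold <= 0 || timeout <= 0 || score_display <= 0 || fps <= 0 ||
    start_radius <= 0 || object_radius <= 0) {
    abort("invalid task configuration", class = "rehabtrack_invalid_argument")
  }
  structure(
    list(
      kind = kind, trials = trials, hold = hold, timeout = timeout,
      score_display = score_display, limb_switch = limb_switch, fps = fps,
      reach_area = reach_area, start_center = as.numeric(start_center),
      start_radius = start_radius, object_radius = object_radius,
      grasp_threshold = grasp_threshold, seed = as.integer(seed)
    ),
    class = "task_config"
  )
}

#' @export
print.task_config <- function(x, ...) {
  cat(sprintf(
    "<task_config> %s: %d trials (limb switch after %d), hold %.1f s, timeout %.1f s\n",
    x$kind, x$trials, x$limb_switch, x$hold, x$timeout
  ))
  invisible(x)
}

#' Spawn target objects uniformly in the reach area
#'
#' Draws positions uniformly over the configured horizontal rectangle at its
#' constant height, using R's global RNG stream (the session driver seeds it
#' from the task seed, so spawn sequences are reproducible).
#'
#' @param cfg A [task_config()] (its `reach_area` is used).
#' @param n Number of positions to draw.
#' @return A tibble (`x`, `y`, `z`), one row per spawn.
#' @export
spawn_targets <- function(cfg, n = 1) {
  area <- cfg$reach_area
  if (any(!is.finite(area$extent)) || any(area$extent <= 0)) {
    abort("degenerate reach area", class = "rehabtrack_invalid_argument")
  }
  tibble(
    x = area$center[1] + (runif(n) - 0.5) * area$extent[1],
    y = area$center[2],
    z = area$center[3] + (runif(n) - 0.5) * area$extent[2]
  )
}

new_trial_state <- function(cfg, trial = 1L, t = 0) {
  list(
    phase = "wait_start", t_phase = t, trial = trial, t_last = -Inf,
    hold_since = NA_real_, spawn_time = NA_real_,
    first_entry = NA_real_, first_exit = NA_real_,
    object = NULL, object1 = NULL, line = NULL,
    pending = NULL, emit = NULL
  )
}

ev_row <- function(time, trial, event, value = NA_real_) {
  data.frame(time = time, trial = trial, event = event, value = value)
}

#' Advance the trial state machine by one observation
#'
#' The deterministic clock-driven core of the task engine: consumes one
#' timestamped hand-center sample (plus the grasp-closure flag) and returns
#' the next state together with the events fired at this step (color-cue
#' changes, spawns, trial outcomes). "Reached within the timeout" is judged
#' on the first entry into object proximity; the subsequent hold may finish
#' after the timeout mark without voiding the trial. The timeout window does
#' not restart if the hand re-enters the start area mid-trial.
#'
#' Most callers want [run_session()] or [simulate_session()], which drive
#' this function over a whole stream and assemble trial records.
#'
#' @param state A trial state as returned by previous calls (create the
#'   initial one with `trial_step(NULL, ...)`'s documented driver
#'   [run_session()]; states are plain lists).
#' @param hand_center Length-3 hand-center position (m).
#' @param grasp Logical grasp-closure flag.
#' @param t Timestamp (s); must be non-decreasing across calls.
#' @param cfg The [task_config()].
#' @return A list with `state` (updated) and `events` (data frame with
#'   columns `time`, `trial`, `event`, `value`, or `NULL`).
#' @export
trial_step <- function(state, hand_center, grasp, t, cfg) {
  if (is.null(state)) state <- new_trial_state(cfg)
  if (t < state$t_last) {
    abort("time must be non-decreasing", class = "rehabtrack_invalid_argument")
  }
  events <- NULL
  emit <- function(event, value = NA_real_) {
    events <<- rbind(events, ev_row(t, state$trial, event, value))
  }
  if (identical(state$t_last, -Inf)) emit("trial_start")
  state$t_last <- t
  eps <- 1e-9
  inside_start <- v_norm(hand_center - cfg$start_center) <= cfg$start_radius
  near <- function(obj) {
    !is.null(obj) && v_norm(hand_center - obj) <= cfg$object_radius
  }
  spawn_reach_target <- function(anchor) {
    obj <- as.numeric(spawn_targets(cfg, 1))
    anchor_pt <- c(anchor[1], obj[2], anchor[3]) # projected to the line plane
    state$object <<- obj
    state$line <<- unname(rbind(anchor_pt, obj))
    state$spawn_time <<- t
    state$first_entry <<- NA_real_
    emit("object_spawn")
  }

  switch(state$phase,
    wait_start = {
      if (inside_start) {
        state$phase <- "hold_start"
        state$hold_since <- t
      }
    },
    hold_start = {
      if (!inside_start) {
        state$phase <- "wait_start"
      } else if (t - state$hold_since >= cfg$hold - eps) {
        emit("start_area_green", t - state$hold_since)
        emit("start_area_gray")
        if (cfg$kind == "grasp") {
          state$object1 <- as.numeric(spawn_targets(cfg, 1))
          state$spawn_time <- t
          state$first_entry <- NA_real_
          state$first_exit <- NA_real_
          state$phase <- "grasp_object1"
          emit("object_spawn")
        } else {
          state$first_exit <- NA_real_
          spawn_reach_target(cfg$start_center)
          state$phase <- "reaching"
        }
      }
    },
    reaching = {
      if (is.na(state$first_exit) && !inside_start) state$first_exit <- t
      if (is.na(state$first_entry)) {
        if (near(state$object)) {
          state$first_entry <- t
          state$hold_since <- t
          state$phase <- "hold_target"
          emit("object_green")
        } else if (t - state$spawn_time >= cfg$timeout - eps) {
          state$pending <- list(outcome = "unfinished", window_end = t)
          emit("trial_unfinished", t - state$spawn_time)
          state$phase <- "return"
          state$object <- NULL
        }
      } else if (near(state$object)) {
        state$phase <- "hold_target"
        state$hold_since <- t
      }
    },
    hold_target = {
      if (!near(state$object)) {
        state$phase <- "reaching"
      } else if (t - state$hold_since >= cfg$hold - eps) {
        state$pending <- list(
          outcome = "finished",
          reach_time = state$first_entry - state$spawn_time,
          window_end = state$first_entry
        )
        emit("trial_finished", state$pending$reach_time)
        state$phase <- "show_score"
        state$t_phase <- t
      }
    },
    grasp_object1 = {
      if (is.na(state$first_exit) && !inside_start) state$first_exit <- t
      grasped <- near(state$object1) && isTRUE(grasp)
      if (is.na(state$first_entry)) {
        if (grasped) {
          state$first_entry <- t
          state$hold_since <- t
          state$phase <- "hold_object1"
          emit("object_green")
        } else if (t - state$spawn_time >= cfg$timeout - eps) {
          state$pending <- list(outcome = "unfinished", window_end = t)
          emit("trial_unfinished", t - state$spawn_time)
          state$phase <- "return"
          state$object1 <- NULL
        }
      } else if (grasped) {
        state$phase <- "hold_object1"
        state$hold_since <- t
      }
    },
    hold_object1 = {
      if (!(near(state$object1) && isTRUE(grasp))) {
        state$phase <- "grasp_object1"
      } else if (t - state$hold_since >= cfg$hold - eps) {
        emit("object_yellow")
        spawn_reach_target(state$object1)
        state$first_exit <- t # movement along the line starts at object 1
        state$phase <- "reaching"
      }
    },
    show_score = {
      if (t - state$t_phase >= cfg$score_display - eps) state$phase <- "return"
    },
    `return` = {
      if (inside_start) {
        emit("start_area_blue")
        if (state$trial >= cfg$trials) {
          state$pending <- NULL
          state$phase <- "done"
        } else {
          tr <- state$trial + 1L
          keep <- state$t_last
          state <- new_trial_state(cfg, trial = tr, t = t)
          state$t_last <- keep
          events <- rbind(events, ev_row(t, tr, "trial_start"))
        }
      }
    },
    done = NULL
  )
  list(state = state, events = events)
}

# shared driver: get_frame(i, view) -> list(t, pos, grasp) or NULL (exhausted)
.drive_session <- function(cfg, get_frame) {
  set.seed(cfg$seed)
  state <- new_trial_state(cfg)
  records <- list()
  events <- list()
  tr_t <- list()
  tr_p <- list()
  tr_g <- list()
  k <- 0L
  trial_first <- 1L
  limb_of <- function(trial) if (trial <= cfg$limb_switch) "left" else "right"

  finalize <- function(pending, st) {
    idx <- seq.int(trial_first, k)
    trace <- tibble(
      time = unlist(tr_t[idx]),
      x = vapply(tr_p[idx], `[`, numeric(1), 1),
      y = vapply(tr_p[idx], `[`, numeric(1), 2),
      z = vapply(tr_p[idx], `[`, numeric(1), 3),
      grasp = unlist(tr_g[idx])
    )
    # movement window: first exit of the start area (falling back to the
    # spawn time if the hand never left it) up to reach or timeout
    wnd <- c(
      if (is.na(st$first_exit)) st$spawn_time else st$first_exit,
      pending$window_end
    )
    avg <- NA_real_
    pkv <- NA_real_
    if (!is.na(wnd[1]) && !is.null(st$line)) {
      inw <- trace$time >= wnd[1] - 1e-9 & trace$time <= wnd[2] + 1e-9
      if (any(inw)) {
        avg <- average_line_distance(trace, st$line, window = wnd)
      }
      if (sum(inw) >= 3) pkv <- peak_velocity(trace, window = wnd)
    }
    score <- if (pending$outcome == "finished") {
      trial_score(avg, "finished")
    } else {
      trial_score(avg, "unfinished")
    }
    trial <- st$trial
    tibble(
      trial = trial, limb = limb_of(trial),
      avatar_limb = if (cfg$kind == "mirrored") {
        setdiff(c("left", "right"), limb_of(trial))
      } else {
        limb_of(trial)
      },
      outcome = pending$outcome,
      spawn_time = st$spawn_time,
      reach_time = pending$reach_time %||% NA_real_,
      window_start = wnd[1], window_end = wnd[2],
      avg_distance = avg, score = score, peak_velocity = pkv,
      object = list(st$object %||% st$object1),
      line = list(st$line),
      trace = list(trace)
    )
  }

  i <- 0L
  repeat {
    i <- i + 1L
    view <- list(
      phase = state$phase, trial = state$trial,
      target = state$object1 %||% state$object,
      line = state$line, spawn_time = state$spawn_time,
      start_center = cfg$start_center
    )
    if (state$phase %in% c("reaching", "hold_target")) view$target <- state$object
    inp <- get_frame(i, view)
    if (is.null(inp)) {
      done_records <- if (length(records)) bind_rows(records) else NULL
      abort(
        sprintf(
          "input stream exhausted after %d completed trials (of %d)",
          length(records), cfg$trials
        ),
        class = "rehabtrack_truncated_session",
        records = done_records, trials_completed = length(records)
      )
    }
    k <- k + 1L
    tr_t[[k]] <- inp$t
    tr_p[[k]] <- inp$pos
    tr_g[[k]] <- isTRUE(inp$grasp)
    before <- state
    res <- trial_step(state, inp$pos, isTRUE(inp$grasp), inp$t, cfg)
    state <- res$state
    if (!is.null(res$events)) {
      events[[length(events) + 1L]] <- res$events
      if (any(res$events$event == "start_area_blue")) {
        # the trial that just completed lives in `before` + its pending stub
        pending <- before$pending
        rec <- finalize(pending, before)
        records[[length(records) + 1L]] <- rec
        if (pending$outcome == "finished") {
          events[[length(events) + 1L]] <-
            ev_row(inp$t, rec$trial, "score_final", rec$score)
        }
        trial_first <- k + 1L
      }
    }
    if (state$phase == "done") break
  }
  structure(
    list(
      config = cfg,
      trials = bind_rows(records),
      events = as_tibble(bind_rows(events))
    ),
    class = "task_session"
  )
}

#' Run a task session over a pre-recorded hand trace
#'
#' Drives the trial state machine over an avatar hand-center stream and
#' assembles one record per trial: active limb (left for the first
#' `limb_switch` trials, then right; mirrored sessions additionally record
#' the contralateral avatar limb), outcome, reach time, the movement-window
#' mean hand-to-line distance, the per-trial score, and the peak hand speed.
#' Identical trace, configuration and seed give bit-identical records.
#'
#' @param trace A tibble with columns `time`, `x`, `y`, `z` and optionally
#'   `grasp` (logical); timestamps non-decreasing.
#' @param cfg A [task_config()].
#' @return A `"task_session"`: list with `config`, `trials` (tibble of trial
#'   records, including per-trial `trace` list column) and `events`. If the
#'   trace ends before all trials complete, a `rehabtrack_truncated_session`
#'   error is raised carrying the completed records.
#' @export
run_session <- function(trace, cfg) {
  if (!all(c("time", "x", "y", "z") %in% names(trace))) {
    abort("trace must have columns time, x, y, z",
      class = "rehabtrack_invalid_argument"
    )
  }
  grasp <- if ("grasp" %in% names(trace)) trace$grasp else rep(FALSE, nrow(trace))
  n <- nrow(trace)
  .drive_session(cfg, function(i, view) {
    if (i > n) {
      return(NULL)
    }
    list(
      t = trace$time[i], pos = c(trace$x[i], trace$y[i], trace$z[i]),
      grasp = grasp[i]
    )
  })
}

#' Simulate a closed-loop task session
#'
#' Generates the hand trace online by querying a behaviour policy once per
#' frame (at `cfg$fps`), which lets the simulated subject react to the
#' randomly spawned targets, then runs the state machine over it. With
#' [policy_line_follower()] the hand tracks each guide line exactly; with
#' [policy_hold_start()] it never leaves the start area and every trial
#' times out.
#'
#' @param cfg A [task_config()].
#' @param policy A function `function(view, t, dt)` returning
#'   `list(pos, grasp)`; see [policy_line_follower()].
#' @param max_time Safety horizon (s); exceeding it raises a
#'   truncated-session error.
#' @return A `"task_session"`, see [run_session()].
#' @examples
#' cfg <- task_config(trials = 2, limb_switch = 1, seed = 42)
#' s <- simulate_session(cfg, policy_line_follower())
#' s$trials$score
#' @export
simulate_session <- function(cfg, policy = policy_line_follower(),
                             max_time = 60 * cfg$trials) {
  dt <- 1 / cfg$fps
  .drive_session(cfg, function(i, view) {
    t <- (i - 1) * dt
    if (t > max_time) {
      return(NULL)
    }
    inp <- policy(view, t, dt)
    inp$t <- t
    inp
  })
}

#' Behaviour policies for simulated sessions
#'
#' `policy_line_follower()` emulates a compliant subject: it waits in the
#' start area, moves along the guide line to each spawned object with a
#' minimum-jerk time course over `reach_time` seconds (staying exactly on
#' the line, so finished trials score the maximum), closes the hand on
#' arrival during grasp trials, and returns to the start area at
#' `return_speed` after each trial. `policy_hold_start()` keeps the hand at
#' the start-area center forever, so every trial times out unfinished.
#'
#' @param reach_time Duration (s) of each reach movement.
#' @param return_speed Return movement speed (m/s).
#' @return A policy function `function(view, t, dt)` for
#'   [simulate_session()].
#' @export
policy_line_follower <- function(reach_time = 2, return_speed = 1.2) {
  pos <- NULL
  origin <- NULL
  t0_key <- NA_real_
  function(view, t, dt) {
    if (is.null(pos)) pos <<- view$start_center
    ph <- view$phase
    if (ph %in% c("reaching", "grasp_object1") && !is.null(view$target)) {
      if (!identical(view$spawn_time, t0_key)) {
        origin <<- pos
        t0_key <<- view$spawn_time
      }
      tau <- min(1, (t - view$spawn_time) / reach_time)
      pos <<- origin + min_jerk_s(tau) * (view$target - origin)
    } else if (ph %in% c("hold_target", "hold_object1") && !is.null(view$target)) {
      pos <<- view$target
    } else if (ph %in% c("wait_start", "show_score", "return")) {
      d <- view$start_center - pos
      nd <- v_norm(d)
      step <- return_speed * dt
      pos <<- if (nd <= step) view$start_center else pos + d / nd * step
    }
    grasp <- ph %in% c("grasp_object1", "hold_object1") &&
      !is.null(view$target) && v_norm(pos - view$target) < 1e-9
    list(pos = pos, grasp = grasp)
  }
}

#' @rdname policy_line_follower
#' @export
policy_hold_start <- function() {
  function(view, t, dt) list(pos = view$start_center, grasp = FALSE)
}

#' @export
print.task_session <- function(x, ...) {
  cat(sprintf(
    "<task_session> %s: %d/%d trials finished, game performance %.1f, unfinished rate %.3f\n",
    x$config$kind, sum(x$trials$outcome == "finished"), nrow(x$trials),
    game_performance(x), unfinished_rate(x)
  ))
  invisible(x)
}
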