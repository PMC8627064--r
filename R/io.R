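# JSONL pose/keypoint stream I/O. One frame per line:
#   3D: {"time": t, "joints": {"left_wrist": [x, y, z, conf], ...}}
#   2D: {"time": t, "camera": "cam_a", "joints": {"left_wrist": [u, v, conf]}}

#' Read and write pose streams as JSONL
#'
#' @param frames A 3D pose tibble (`time`, `joint`, `x`, `y`, `z`, `conf`).
#' @param path File path.
#' @return Readers return tibbles; writers return `path` invisibly.
#' @export
pose_write_jsonl <- function(frames, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in split(frames, frames$time)) {
    joints <- lapply(seq_len(nrow(fr)), function(i) {
      c(fr$x[i], fr$y[i], fr$z[i], fr$conf[i])
    })
    names(joints) <- fr$joint
    writeLines(jsonlite::toJSON(
      list(time = fr$time[1], joints = joints),
      auto_unbox = TRUE, digits = NA, na = "null"
    ), con)
  }
  invisible(path)
}

#' @rdname pose_write_jsonl
#' @export
pose_read_jsonl <- function(path) {
  rows <- lapply(readLines(path), function(line) {
    doc <- jsonlite::fromJSON(line)
    m <- do.call(rbind, doc$joints)
    tibble(
      time = doc$time, joint = names(doc$joints),
      x = m[, 1], y = m[, 2], z = m[, 3], conf = m[, 4]
    )
  })
  bind_rows(rows)
}

#' Read and write keypoint streams as JSONL
#'
#' @param keypoints A keypoint tibble (`time`, `camera`, `joint`, `u`, `v`,
#'   `conf`).
#' @param path File path.
#' @return Readers return tibbles; writers return `path` invisibly.
#' @export
keypoints_write_jsonl <- function(keypoints, path) {
  con <- file(path, "w")
  on.exit(close(con))
  keypoints <- keypoints %>% arrange(.data$camera, .data$time)
  for (fr in split(
    keypoints,
    interaction(keypoints$camera, keypoints$time, drop = TRUE)
  )) {
    joints <- lapply(seq_len(nrow(fr)), function(i) c(fr$u[i], fr$v[i], fr$conf[i]))
    names(joints) <- fr$joint
    writeLines(jsonlite::toJSON(
      list(time = fr$time[1], camera = fr$camera[1], joints = joints),
      auto_unbox = TRUE, digits = NA, na = "null"
    ), con)
  }
  invisible(path)
}

#' @rdname keypoints_write_jsonl
#' @export
keypoints_read_jsonl <- function(path) {
  rows <- lapply(readLines(path), function(line) {
    doc <- jsonlite::fromJSON(line)
    m <- do.call(rbind, lapply(doc$joints, function(j) {
      j <- unlist(j)
      if (is.null(j) || length(j) < 3) c(NA_real_, NA_real_, 0) else as.numeric(j)
    }))
    tibble(
      time = doc$time, camera = doc$camera, joint = names(doc$joints),
      u = m[, 1], v = m[, 2], conf = m[, 3]
    )
  })
  bind_rows(rows)
}

#' Read a task configuration from YAML
#'
#' The YAML keys mirror the arguments of [task_config()] field for field;
#' absent keys keep the defaults.
#'
#' @param path File path.
#' @return A `"task_config"`.
#' @export
task_config_read <- function(path) {
  doc <- yaml::read_yaml(path)
  if (!is.null(doc$reach_area)) {
    doc$reach_area <- list(
      center = as.numeric(doc$reach_area$center),
      extent = as.numeric(doc$reach_area$extent)
    )
  }
  if (!is.null(doc$start_center)) doc$start_center <- as.numeric(doc$start_center)
  do.call(task_config, doc)
}

#' Read a motion script from YAML
#'
#' Keys mirror [motion_script()]; `start` and `target` are 3-element lists.
#'
#' @param path File path.
#' @return A `"motion_script"`.
#' @export
motion_script_read <- function(path) {
  doc <- yaml::read_yaml(path)
  doc$start <- as.numeric(doc$start)
  doc$target <- as.numeric(doc$target)
  do.call(motion_script, doc)
}

#' Write a session to JSON
#'
#' Stores the configuration echo, the per-trial records (without the heavy
#' frame traces) and the event log.
#'
#' @param session A `"task_session"`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
session_write_json <- function(session, path) {
  jsonlite::write_json(
    list(
      config = unclass(session$config),
      trials = as.data.frame(tidy(session)),
      events = as.data.frame(session$events),
      game_performance = game_performance(session),
      unfinished_rate = unfinished_rate(session)
    ),
    path,
    auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE
  )
  invisible(path)
}
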