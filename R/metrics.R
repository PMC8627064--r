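#' Mean hand-to-line distance during the movement
#'
#' Implements the average-distance definition underlying the trial score:
#' each hand-center sample in the movement window is mapped onto the
#' horizontal plane at the guide line's height (so vertical offsets do not
#' count), the perpendicular distance to the guide line segment is taken,
#' and the per-frame distances are averaged arithmetically.
#'
#' @param trace A tibble with columns `time`, `x`, `y`, `z`.
#' @param line The guide line as a 2 x 3 matrix (rows: start, end) or a
#'   two-row data frame with `x`, `y`, `z`.
#' @param window Optional `c(t0, t1)` restricting the trace to the movement
#'   window; `NULL` uses all frames.
#' @return Mean distance (m).
#' @export
average_line_distance <- function(trace, line, window = NULL) {
  line <- as_line(line)
  tr <- window_trace(trace, window)
  if (nrow(tr) == 0) {
    abort("no frames in the movement window",
      class = "rehabtrack_no_movement_frames"
    )
  }
  plane_y <- mean(line[, 2])
  a <- c(line[1, 1], plane_y, line[1, 3])
  b <- c(line[2, 1], plane_y, line[2, 3])
  d <- vapply(seq_len(nrow(tr)), function(i) {
    point_segment_distance(c(tr$x[i], plane_y, tr$z[i]), a, b)
  }, numeric(1))
  mean(d)
}

as_line <- function(line) {
  if (is.data.frame(line)) line <- as.matrix(line[, c("x", "y", "z")])
  line <- as.matrix(line)
  if (!all(dim(line) == c(2, 3))) {
    abort("a line is two 3D points", class = "rehabtrack_invalid_argument")
  }
  line
}

window_trace <- function(trace, window) {
  if (is.null(window)) {
    return(trace)
  }
  trace[trace$time >= window[1] - 1e-9 & trace$time <= window[2] + 1e-9, ]
}

#' Per-trial score from the average line distance
#'
#' `score = (0.1 - average distance) * 1000`, clamped to \[0, 100\]:
#' a trial tracked exactly on the guide line scores the maximum of 100 and
#' the score falls linearly to 0 at a 10 cm mean deviation (distances are in
#' meters). Unfinished trials score 0 regardless of distance.
#'
#' @param avg_distance Mean hand-to-line distance (m), >= 0 for finished
#'   trials; see [average_line_distance()].
#' @param outcome `"finished"` or `"unfinished"` (vectorized, recycled).
#' @return Score in \[0, 100\].
#' @examples
#' trial_score(0, "finished") # 100
#' trial_score(0.05, "finished") # 50
#' @export
trial_score <- function(avg_distance, outcome = c("finished", "unfinished")) {
  if (length(outcome) == 1) outcome <- match.arg(outcome)
  n <- max(length(avg_distance), length(outcome))
  avg_distance <- rep_len(avg_distance, n)
  outcome <- rep_len(outcome, n)
  fin <- outcome == "finished"
  if (any(fin & !is.na(avg_distance) & avg_distance < 0)) {
    abort("average distance must be non-negative",
      class = "rehabtrack_invalid_argument"
    )
  }
  out <- numeric(n)
  out[fin] <- pmin(100, pmax(0, (0.1 - avg_distance[fin]) * 1000))
  out[!fin] <- 0
  out
}

#' Total game performance of a session
#'
#' The sum of the per-trial scores; with the default 30 trials the maximum
#' is 3000, attained only when every trial is finished with zero mean
#' line distance.
#'
#' @param x A `"task_session"`, or a trial-records data frame with a
#'   `score` column.
#' @return Total score.
#' @export
game_performance <- function(x) {
  trials <- if (inherits(x, "task_session")) x$trials else x
  if (nrow(trials) == 0) {
    return(0)
  }
  sum(trials$score)
}

#' Peak hand speed over the movement window
#'
#' Speeds are estimated by central finite differences on the position trace,
#' smoothed with a 5-sample moving average (skipped when fewer than five
#' speed samples exist), and the maximum over the window is returned. For a
#' minimum-jerk reach of distance d over T seconds the peak approaches
#' `1.875 d / T` as the frame rate grows.
#'
#' @param trace A tibble with columns `time`, `x`, `y`, `z`; strictly
#'   increasing timestamps, at least 3 frames in the window.
#' @param window Optional `c(t0, t1)` movement window.
#' @param smooth Moving-average width in samples.
#' @return Peak speed (m/s).
#' @export
peak_velocity <- function(trace, window = NULL, smooth = 5) {
  tr <- window_trace(trace, window)
  n <- nrow(tr)
  if (n < 3) {
    abort("at least 3 frames are needed to estimate a velocity peak",
      class = "rehabtrack_too_few_frames"
    )
  }
  if (is.unsorted(tr$time, strictly = TRUE)) {
    abort("timestamps must be strictly increasing",
      class = "rehabtrack_invalid_argument"
    )
  }
  p <- as.matrix(tr[, c("x", "y", "z")])
  i <- 2:(n - 1)
  v <- sqrt(rowSums((p[i + 1, , drop = FALSE] - p[i - 1, , drop = FALSE])^2)) /
    (tr$time[i + 1] - tr$time[i - 1])
  if (length(v) >= smooth) {
    sm <- stats::filter(v, rep(1 / smooth, smooth), sides = 2)
    v <- as.numeric(sm[!is.na(sm)])
  }
  max(v)
}

#' Fraction of unfinished trials
#'
#' @param x A `"task_session"` or a trial-records data frame with an
#'   `outcome` column; must hold at least one trial.
#' @return Fraction in \[0, 1\].
#' @export
unfinished_rate <- function(x) {
  trials <- if (inherits(x, "task_session")) x$trials else x
  if (nrow(trials) == 0) {
    abort("unfinished rate is undefined for an empty session",
      class = "rehabtrack_invalid_argument"
    )
  }
  mean(trials$outcome == "unfinished")
}

#' Outcome-measure report for a session
#'
#' Bundles the per-trial measures (score, reach time, mean line distance,
#' peak hand speed) with the session totals (game performance, unfinished
#' rate).
#'
#' @param session A `"task_session"`.
#' @return A list of class `"metrics_report"` with `trials` (tibble),
#'   `game_performance` and `unfinished_rate`.
#' @export
session_metrics <- function(session) {
  stopifnot(inherits(session, "task_session"))
  trials <- session$trials %>%
    select(
      "trial", "limb", "avatar_limb", "outcome", "reach_time",
      "avg_distance", "score", "peak_velocity"
    )
  structure(
    list(
      trials = trials,
      game_performance = game_performance(session),
      unfinished_rate = unfinished_rate(session)
    ),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "<metrics_report> %d trials: game performance %.1f, unfinished rate %.3f\n",
    nrow(x$trials), x$game_performance, x$unfinished_rate
  ))
  print(x$trials, n = 5)
  invisible(x)
}

#' Write a session metrics report as CSV
#'
#' One row per trial plus footer rows for the session totals.
#'
#' @param report A `"metrics_report"` (or a `"task_session"`, which is
#'   summarised first).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(report, path) {
  if (inherits(report, "task_session")) report <- session_metrics(report)
  df <- as.data.frame(report$trials)
  con <- file(path, "w")
  on.exit(close(con))
  write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  cat(sprintf("game_performance,%.6f\n", report$game_performance), file = con)
  cat(sprintf("unfinished_rate,%.6f\n", report$unfinished_rate), file = con)
  invisible(path)
}
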