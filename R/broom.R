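#' Tidy a task session into per-trial records
#'
#' @param x A `"task_session"`.
#' @param ... Unused.
#' @return A tibble with one row per trial (heavy list columns dropped).
#' @method tidy task_session
#' @export
tidy.task_session <- function(x, ...) {
  x$trials %>%
    select(
      "trial", "limb", "avatar_limb", "outcome", "spawn_time", "reach_time",
      "avg_distance", "score", "peak_velocity"
    )
}

#' One-row summary of a task session
#'
#' @param x A `"task_session"`.
#' @param ... Unused.
#' @return A one-row tibble: trial counts, game performance, unfinished
#'   rate, mean score and mean peak speed over finished trials.
#' @method glance task_session
#' @export
glance.task_session <- function(x, ...) {
  tr <- x$trials
  fin <- tr$outcome == "finished"
  tibble(
    kind = x$config$kind,
    n_trials = nrow(tr),
    n_finished = sum(fin),
    unfinished_rate = unfinished_rate(x),
    game_performance = game_performance(x),
    mean_score = mean(tr$score),
    mean_peak_velocity = mean(tr$peak_velocity[fin])
  )
}

#' Plot per-trial scores of a session
#'
#' @param object A `"task_session"`.
#' @param ... Unused.
#' @return A ggplot: score per trial, colored by outcome, with the limb
#'   switch marked.
#' @method autoplot task_session
#' @export
autoplot.task_session <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$trial, y = .data$score,
    fill = .data$outcome
  )) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(
      xintercept = object$config$limb_switch + 0.5,
      linetype = "dashed"
    ) +
    ggplot2::labs(
      x = "trial", y = "score",
      title = sprintf("%s task: per-trial scores", object$config$kind),
      subtitle = sprintf(
        "game performance %.0f, unfinished rate %.2f (dashed line: limb switch)",
        game_performance(object), unfinished_rate(object)
      )
    ) +
    ggplot2::ylim(0, 100)
}

#' Plot one trial's hand path against its guide line
#'
#' Top view (x against z, the horizontal plane the score is computed in) of
#' the hand-center trace, the guide line, the target object and the start
#' area.
#'
#' @param session A `"task_session"`.
#' @param trial Trial index.
#' @return A ggplot.
#' @export
plot_trial <- function(session, trial = 1) {
  rec <- session$trials[session$trials$trial == trial, ]
  if (nrow(rec) != 1) {
    abort("no such trial", class = "rehabtrack_invalid_argument")
  }
  tr <- rec$trace[[1]]
  ln <- rec$line[[1]]
  obj <- rec$object[[1]]
  cfg <- session$config
  p <- ggplot2::ggplot(tr, ggplot2::aes(x = .data$x, y = .data$z)) +
    ggplot2::geom_path(color = "grey40") +
    ggplot2::annotate("point",
      x = cfg$start_center[1], y = cfg$start_center[3],
      shape = 1, size = 6, color = "blue"
    ) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "x (m)", y = "z (m)",
      title = sprintf(
        "trial %d (%s, %s): score %.1f", trial, rec$limb, rec$outcome,
        rec$score
      )
    )
  if (!is.null(ln)) {
    p <- p + ggplot2::annotate("segment",
      x = ln[1, 1], y = ln[1, 3], xend = ln[2, 1], yend = ln[2, 3],
      color = "steelblue"
    )
  }
  if (!is.null(obj)) {
    p <- p + ggplot2::annotate("point",
      x = obj[1], y = obj[3], color = "darkgreen", size = 3
    )
  }
  p
}
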