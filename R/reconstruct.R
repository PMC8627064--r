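# vectorized ray-midpoint triangulation of paired observations
# uv_a, uv_b: n x 2 pixel matrices. Returns points (n x 3), residual (n),
# ok flag (FALSE where the back-projected rays are numerically parallel).
.triangulate_many <- function(uv_a, cam_a, uv_b, cam_b) {
  ra <- .backproject(cam_a, uv_a)
  rb <- .backproject(cam_b, uv_b)
  n <- nrow(uv_a)
  D1 <- ra$dirs
  D2 <- rb$dirs
  w0 <- matrix(ra$origin - rb$origin, n, 3, byrow = TRUE)
  b <- rowSums(D1 * D2)
  d <- rowSums(D1 * w0)
  e <- rowSums(D2 * w0)
  denom <- 1 - b^2 # == |d1 x d2|^2 for unit directions
  ok <- is.finite(denom) & denom > 1e-24
  s <- (b * e - d) / denom
  tt <- (e - b * d) / denom
  P1 <- matrix(ra$origin, n, 3, byrow = TRUE) + D1 * s
  P2 <- matrix(rb$origin, n, 3, byrow = TRUE) + D2 * tt
  list(
    points = (P1 + P2) / 2,
    residual = sqrt(rowSums((P1 - P2)^2)),
    ok = ok
  )
}

#' Triangulate one joint from a pair of camera observations
#'
#' Back-projects each pixel observation to a world-space ray and returns the
#' midpoint of the shortest segment between the two rays (ray-midpoint
#' method). The segment length is returned as the residual; it is a natural
#' reconstruction-quality score and is zero when the rays intersect exactly.
#'
#' @param uv_a,uv_b Length-2 pixel coordinates `(u, v)` in each camera.
#' @param cam_a,cam_b The two `"camera_model"`s; their centers must be
#'   distinct and the back-projected rays must not be parallel.
#' @return A list with `point` (length-3, m) and `residual` (m).
#' @examples
#' rig <- default_rig()
#' p <- c(0, 1.2, 1.6)
#' obs_a <- as.numeric(project_points(rig$a, rbind(p)))
#' obs_b <- as.numeric(project_points(rig$b, rbind(p)))
#' triangulate(obs_a, rig$a, obs_b, rig$b)$point # recovers p
#' @export
triangulate <- function(uv_a, cam_a, uv_b, cam_b) {
  if (!all(is.finite(c(uv_a, uv_b)))) {
    abort("observations must be finite", class = "rehabtrack_invalid_argument")
  }
  if (v_norm(camera_center(cam_a) - camera_center(cam_b)) < 1e-12) {
    abort("camera centers coincide: geometry is degenerate",
      class = "rehabtrack_degenerate_geometry"
    )
  }
  res <- .triangulate_many(rbind(uv_a), cam_a, rbind(uv_b), cam_b)
  if (!res$ok[1]) {
    abort("back-projected rays are parallel: geometry is degenerate",
      class = "rehabtrack_degenerate_geometry"
    )
  }
  list(point = res$points[1, ], residual = res$residual[1])
}

#' Fuse two-camera keypoint streams into a 3D pose stream
#'
#' Pairs the two cameras' frames by timestamp (tolerance: half a frame
#' period) and triangulates every joint seen in both. A joint dropped in
#' either camera gets confidence 0 and `NA` position in that frame (filled
#' downstream by the gap policy of [filter_stream()]); a joint seen in both
#' keeps the minimum of the two confidences.
#'
#' @param keypoints A keypoint tibble (`time`, `camera`, `joint`, `u`, `v`,
#'   `conf`) containing both cameras of `rig`, e.g. from
#'   [render_keypoints()].
#' @param rig The `"camera_rig"` that produced the observations.
#' @param frame_period Nominal frame period (s) used for the pairing
#'   tolerance; defaults to the median timestamp spacing.
#' @return A 3D pose tibble (`time`, `joint`, `x`, `y`, `z`, `conf`,
#'   `residual`).
#' @export
fuse_streams <- function(keypoints, rig, frame_period = NULL) {
  ids <- c(rig$a$id, rig$b$id)
  if (!setequal(unique(keypoints$camera), ids)) {
    abort("keypoint stream camera ids do not match the rig",
      class = "rehabtrack_invalid_argument"
    )
  }
  ka <- keypoints[keypoints$camera == ids[1], ]
  kb <- keypoints[keypoints$camera == ids[2], ]
  ta <- sort(unique(ka$time))
  tb <- sort(unique(kb$time))
  if (length(ta) != length(tb)) {
    abort("the two camera streams have different frame counts",
      class = "rehabtrack_invalid_argument"
    )
  }
  if (is.null(frame_period)) {
    frame_period <- if (length(ta) > 1) median(diff(ta)) else 1 / 30
  }
  if (max(abs(ta - tb)) > frame_period / 2) {
    abort("camera streams are not synchronised within half a frame period",
      class = "rehabtrack_invalid_argument"
    )
  }
  ka$frame <- match(ka$time, ta)
  kb$frame <- match(kb$time, tb)
  m <- inner_join(
    ka %>% select("frame", "time", "joint", ua = "u", va = "v", ca = "conf"),
    kb %>% select("frame", "joint", ub = "u", vb = "v", cb = "conf"),
    by = c("frame", "joint")
  )
  both <- m$ca > 0 & m$cb > 0
  x <- y <- z <- resid <- rep(NA_real_, nrow(m))
  conf <- numeric(nrow(m))
  if (any(both)) {
    tri <- .triangulate_many(
      cbind(m$ua[both], m$va[both]), rig$a,
      cbind(m$ub[both], m$vb[both]), rig$b
    )
    good <- tri$ok
    idx <- which(both)[good]
    x[idx] <- tri$points[good, 1]
    y[idx] <- tri$points[good, 2]
    z[idx] <- tri$points[good, 3]
    resid[idx] <- tri$residual[good]
    conf[idx] <- pmin(m$ca, m$cb)[idx]
  }
  tibble(
    time = m$time, joint = m$joint,
    x = x, y = y, z = z, conf = conf, residual = resid
  ) %>% arrange(.data$time)
}

#' @rdname fuse_streams
#' @param frame_a,frame_b Single-frame keypoint tibbles, one per camera.
#' @export
fuse_frame <- function(frame_a, frame_b, rig, frame_period = NULL) {
  fuse_streams(bind_rows(frame_a, frame_b), rig, frame_period = frame_period)
}

#' Smoothing parameters for reconstructed pose streams
#'
#' The default is the One-Euro filter, a causal adaptive low-pass filter
#' widely used for low-latency pose smoothing: the cutoff rises with the
#' estimated signal speed, so slow drift is smoothed hard while fast motion
#' passes with little lag. `"ema"` is a plain exponential moving average and
#' `"none"` returns the input untouched.
#'
#' @param kind `"one_euro"`, `"ema"` or `"none"`.
#' @param min_cutoff One-Euro minimum cutoff (Hz), > 0.
#' @param beta One-Euro speed coefficient, >= 0. The default of 20 is scaled
#'   for signals in meters moving at tenths of m/s (the cutoff rises by
#'   `beta` Hz per m/s of estimated speed), keeping the lag on reach-speed
#'   motion below the stereo noise floor.
#' @param d_cutoff One-Euro derivative cutoff (Hz), > 0.
#' @param alpha EMA smoothing factor in (0, 1].
#' @param conf_decay Multiplicative per-frame confidence decay applied to
#'   gap-filled samples, signalling staleness downstream.
#' @return A list of class `"filter_params"`.
#' @export
filter_params <- function(kind = c("one_euro", "ema", "none"),
                          min_cutoff = 1.0, beta = 20, d_cutoff = 1.0,
                          alpha = 0.3, conf_decay = 0.9) {
  kind <- match.arg(kind)
  if (min_cutoff <= 0 || d_cutoff <= 0 || beta < 0 ||
    alpha <= 0 || alpha > 1 || conf_decay < 0 || conf_decay > 1) {
    abort("invalid filter parameters", class = "rehabtrack_invalid_argument")
  }
  structure(
    list(
      kind = kind, min_cutoff = min_cutoff, beta = beta,
      d_cutoff = d_cutoff, alpha = alpha, conf_decay = conf_decay
    ),
    class = "filter_params"
  )
}

# One-Euro filter over one scalar series sampled at times t
.one_euro <- function(t, x, min_cutoff, beta, d_cutoff) {
  n <- length(x)
  y <- numeric(n)
  y[1] <- x[1]
  dx_hat <- 0
  smooth_alpha <- function(cutoff, dt) {
    tau <- 1 / (2 * pi * cutoff)
    1 / (1 + tau / dt)
  }
  if (n > 1) {
    for (i in 2:n) {
      dt <- t[i] - t[i - 1]
      dx <- (x[i] - y[i - 1]) / dt
      ad <- smooth_alpha(d_cutoff, dt)
      dx_hat <- ad * dx + (1 - ad) * dx_hat
      a <- smooth_alpha(min_cutoff + beta * abs(dx_hat), dt)
      y[i] <- a * x[i] + (1 - a) * y[i - 1]
    }
  }
  y
}

.ema <- function(x, alpha) {
  n <- length(x)
  y <- numeric(n)
  y[1] <- x[1]
  if (n > 1) for (i in 2:n) y[i] <- y[i - 1] + alpha * (x[i] - y[i - 1])
  y
}

#' Causally smooth a 3D pose stream
#'
#' Applies the configured filter per joint and per axis, in time order.
#' Frames where a joint has confidence 0 are gap-filled with the last
#' confident filtered value and their confidence decays multiplicatively
#' (`conf_decay` per frame); gaps before the first confident sample are
#' back-filled with that first sample at confidence 0. With `kind = "none"`
#' the input is returned unchanged. Output length always equals input
#' length, and a constant-position stream passes through untouched.
#'
#' @param frames A 3D pose tibble with strictly increasing frame timestamps.
#' @param params A [filter_params()] object.
#' @return The smoothed pose tibble, same shape and timestamps.
#' @export
filter_stream <- function(frames, params = filter_params()) {
  tms <- unique(frames$time)
  if (is.unsorted(tms, strictly = TRUE)) {
    abort("frame timestamps must be strictly increasing",
      class = "rehabtrack_invalid_argument"
    )
  }
  if (params$kind == "none") {
    return(frames)
  }
  out <- frames %>% arrange(.data$time)
  for (j in unique(out$joint)) {
    sel <- which(out$joint == j)
    tj <- out$time[sel]
    conf <- out$conf[sel]
    obs <- conf > 0
    if (!any(obs)) next
    first_obs <- which(obs)[1]
    for (col in c("x", "y", "z")) {
      v <- out[[col]][sel]
      sm <- if (params$kind == "one_euro") {
        .one_euro(tj[obs], v[obs], params$min_cutoff, params$beta, params$d_cutoff)
      } else {
        .ema(v[obs], params$alpha)
      }
      filled <- numeric(length(v))
      filled[obs] <- sm
      last <- sm[1]
      k <- 0
      for (i in seq_along(v)) {
        if (obs[i]) {
          last <- filled[i]
          k <- k + 1
        } else {
          filled[i] <- if (i < first_obs) sm[1] else last
        }
      }
      out[[col]][sel] <- filled
    }
    new_conf <- conf
    last_c <- 0
    for (i in seq_along(conf)) {
      if (obs[i]) {
        last_c <- conf[i]
      } else {
        last_c <- last_c * params$conf_decay
        new_conf[i] <- if (i < first_obs) 0 else last_c
      }
    }
    out$conf[sel] <- new_conf
  }
  out
}
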