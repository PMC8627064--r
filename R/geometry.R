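# Internal 3-vector and quaternion arithmetic. Vectors are plain length-3
# numerics; quaternions are length-4 numerics (w, x, y, z), unit unless noted.

v_norm <- function(v) sqrt(sum(v * v))

v_unit <- function(v) {
  n <- v_norm(v)
  if (n < 1e-300) {
    abort("cannot normalise a zero-length vector", class = "rehabtrack_zero_vector")
  }
  v / n
}

v_cross <- function(a, b) {
  c(
    a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1]
  )
}

# deterministic unit vector perpendicular to v
v_perp <- function(v) {
  a <- v_cross(v, c(0, 0, 1))
  if (v_norm(a) < 1e-9) a <- v_cross(v, c(0, 1, 0))
  v_unit(a)
}

quat_identity <- function() c(1, 0, 0, 0)

quat_normalize <- function(q) q / sqrt(sum(q * q))

quat_conj <- function(q) c(q[1], -q[2], -q[3], -q[4])

quat_mul <- function(p, q) {
  c(
    p[1] * q[1] - p[2] * q[2] - p[3] * q[3] - p[4] * q[4],
    p[1] * q[2] + p[2] * q[1] + p[3] * q[4] - p[4] * q[3],
    p[1] * q[3] - p[2] * q[4] + p[3] * q[1] + p[4] * q[2],
    p[1] * q[4] + p[2] * q[3] - p[3] * q[2] + p[4] * q[1]
  )
}

# rotate v by unit quaternion q (Rodrigues via two cross products)
quat_rotate <- function(q, v) {
  u <- q[2:4]
  v + 2 * v_cross(u, v_cross(u, v) + q[1] * v)
}

quat_axis_angle <- function(axis, angle) {
  axis <- v_unit(axis)
  c(cos(angle / 2), sin(angle / 2) * axis)
}

# Minimal rotation carrying unit vector `from` onto unit vector `to`. The
# antipodal case (to == -from) has no unique minimal axis; it falls back to a
# half-turn about `fallback_axis` (default: a deterministic perpendicular).
quat_between <- function(from, to, fallback_axis = NULL) {
  d <- sum(from * to)
  if (d < -1 + 1e-12) {
    ax <- if (is.null(fallback_axis)) v_perp(from) else v_unit(fallback_axis)
    return(quat_axis_angle(ax, pi))
  }
  quat_normalize(c(1 + d, v_cross(from, to)))
}

# reflect points (n x 3 matrix) across the plane through `point` with unit
# normal `normal`
reflect_points <- function(p, point, normal) {
  d <- (p[, 1] - point[1]) * normal[1] +
    (p[, 2] - point[2]) * normal[2] +
    (p[, 3] - point[3]) * normal[3]
  p - 2 * outer(d, normal)
}

# minimum-jerk position profile s(tau) on [0, 1]; peak speed of the scaled
# trajectory d * s(t/T) is 1.875 * d / T at tau = 1/2
min_jerk_s <- function(tau) tau^3 * (10 - 15 * tau + 6 * tau^2)

# distance from point p to the segment [a, b]
point_segment_distance <- function(p, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 < 1e-300) {
    return(v_norm(p - a))
  }
  tt <- sum((p - a) * ab) / len2
  tt <- min(max(tt, 0), 1)
  v_norm(p - (a + tt * ab))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
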