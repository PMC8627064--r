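#' Pinhole camera model
#'
#' Intrinsics are in pixels; extrinsics map world coordinates to the camera
#' frame as `p_cam = R p + t` with the camera looking along its +z axis.
#'
#' @param fx,fy Focal lengths (px), must be positive.
#' @param cx,cy Principal point (px).
#' @param width,height Image size (px).
#' @param rotation 3x3 world-to-camera rotation; must be orthonormal with
#'   determinant +1 (tolerance 1e-9).
#' @param translation World-to-camera translation (m).
#' @param id Camera identifier string.
#' @return An object of class `"camera_model"`.
#' @export
camera_model <- function(fx, fy, cx, cy, width, height, rotation, translation,
                         id = "cam") {
  if (fx <= 0 || fy <= 0) {
    abort("focal lengths must be positive", class = "rehabtrack_invalid_argument")
  }
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3, 3)) ||
    max(abs(crossprod(rotation) - diag(3))) > 1e-9 ||
    abs(det(rotation) - 1) > 1e-9) {
    abort("rotation must be a proper orthonormal 3x3 matrix",
      class = "rehabtrack_invalid_argument"
    )
  }
  structure(
    list(
      fx = fx, fy = fy, cx = cx, cy = cy, width = width, height = height,
      R = rotation, t = as.numeric(translation), id = id
    ),
    class = "camera_model"
  )
}

#' @export
print.camera_model <- function(x, ...) {
  ctr <- camera_center(x)
  cat(sprintf(
    "<camera_model> %s  f=(%.0f, %.0f) px  %dx%d  center=(%.2f, %.2f, %.2f) m\n",
    x$id, x$fx, x$fy, x$width, x$height, ctr[1], ctr[2], ctr[3]
  ))
  invisible(x)
}

#' Place a camera by look-at construction
#'
#' @param id Camera identifier.
#' @param center Camera center in world coordinates (m).
#' @param target World point on the optical axis.
#' @param fx,fy,width,height,cx,cy Intrinsics, see [camera_model()].
#' @param up Approximate world up direction used to fix the roll.
#' @return A `"camera_model"`.
#' @export
camera_lookat <- function(id, center, target, fx = 1100, fy = 1100,
                          width = 1280, height = 1024,
                          cx = width / 2, cy = height / 2, up = c(0, 1, 0)) {
  zc <- v_unit(target - center)
  xc <- v_cross(up, zc)
  if (v_norm(xc) < 1e-9) {
    abort("camera optical axis is collinear with the up direction",
      class = "rehabtrack_invalid_argument"
    )
  }
  xc <- v_unit(xc)
  yc <- v_cross(zc, xc)
  R <- rbind(xc, yc, zc)
  dimnames(R) <- NULL
  camera_model(fx, fy, cx, cy, width, height, R, -drop(R %*% center), id = id)
}

#' Camera center in world coordinates
#' @param cam A `"camera_model"`.
#' @return Length-3 numeric (m).
#' @export
camera_center <- function(cam) -drop(crossprod(cam$R, cam$t))

#' The default two-camera capture rig
#'
#' Reproduces the deployed capture geometry: two cameras on tripods about
#' 2 m above the floor, 1.4 m apart, aimed at a subject seated roughly 1.6 m
#' away. World frame: meters, y-up, origin on the floor midway between the
#' cameras' floor projections.
#'
#' @param separation Distance between the camera centers (m).
#' @param height Camera height above the floor (m).
#' @param subject_distance Nominal subject distance from the camera plane (m).
#' @param look_at World point both cameras are aimed at.
#' @param ... Further intrinsics passed to [camera_lookat()].
#' @return A list of class `"camera_rig"` with cameras `a` and `b` and the
#'   rig geometry.
#' @export
default_rig <- function(separation = 1.4, height = 2.0, subject_distance = 1.6,
                        look_at = c(0, 1.2, subject_distance), ...) {
  structure(
    list(
      a = camera_lookat("cam_a", c(-separation / 2, height, 0), look_at, ...),
      b = camera_lookat("cam_b", c(separation / 2, height, 0), look_at, ...),
      separation = separation, height = height,
      subject_distance = subject_distance
    ),
    class = "camera_rig"
  )
}

#' @export
print.camera_rig <- function(x, ...) {
  cat(sprintf(
    "<camera_rig> separation %.2f m, height %.2f m, subject ~%.2f m\n",
    x$separation, x$height, x$subject_distance
  ))
  print(x$a)
  print(x$b)
  invisible(x)
}

# internal matrix projection: pts n x 3 -> n x 2, errors behind the camera
.project_matrix <- function(cam, pts) {
  pc <- pts %*% t(cam$R) + matrix(cam$t, nrow(pts), 3, byrow = TRUE)
  if (any(pc[, 3] <= 1e-12)) {
    abort("point at non-positive depth cannot be projected",
      class = "rehabtrack_behind_camera"
    )
  }
  cbind(
    cam$fx * pc[, 1] / pc[, 3] + cam$cx,
    cam$fy * pc[, 2] / pc[, 3] + cam$cy
  )
}

#' Project world points through a pinhole camera
#'
#' Standard pinhole projection `u = fx x/z + cx`, `v = fy y/z + cy` in the
#' camera frame. Points at non-positive depth raise a behind-camera error.
#'
#' @param cam A `"camera_model"`.
#' @param pts An `n x 3` matrix or a data frame with columns `x`, `y`, `z`.
#' @return A tibble with columns `u`, `v` (pixels).
#' @examples
#' cam <- camera_model(1000, 1000, 500, 500, 1000, 1000, diag(3), c(0, 0, 0))
#' project_points(cam, rbind(c(0.1, 0, 1))) # u = 600, v = 500
#' @export
project_points <- function(cam, pts) {
  if (is.data.frame(pts)) pts <- as.matrix(pts[, c("x", "y", "z")])
  if (is.null(dim(pts))) pts <- matrix(pts, nrow = 1)
  uv <- .project_matrix(cam, pts)
  tibble(u = uv[, 1], v = uv[, 2])
}

# back-project pixels to world rays: list(origin, dirs n x 3 unit)
.backproject <- function(cam, uv) {
  d_cam <- cbind((uv[, 1] - cam$cx) / cam$fx, (uv[, 2] - cam$cy) / cam$fy, 1)
  d_world <- d_cam %*% cam$R # rows times R == t(R) %*% col
  d_world <- d_world / sqrt(rowSums(d_world^2))
  list(origin = camera_center(cam), dirs = d_world)
}

#' Read or write a camera rig as YAML
#'
#' The YAML document stores, per camera, the intrinsics and the row-major
#' world-to-camera rotation and translation, plus the rig geometry summary.
#'
#' @param path File path.
#' @param rig A `"camera_rig"`.
#' @return `rig_read()` returns a `"camera_rig"`; `rig_write()` returns
#'   `path` invisibly.
#' @export
rig_read <- function(path) {
  doc <- yaml::read_yaml(path)
  mk <- function(cm) {
    camera_model(
      cm$fx, cm$fy, cm$cx, cm$cy, cm$width, cm$height,
      matrix(unlist(cm$rotation), 3, 3, byrow = TRUE),
      unlist(cm$translation),
      id = cm$id
    )
  }
  structure(
    list(
      a = mk(doc$cameras[[1]]), b = mk(doc$cameras[[2]]),
      separation = doc$separation, height = doc$height,
      subject_distance = doc$subject_distance
    ),
    class = "camera_rig"
  )
}

#' @rdname rig_read
#' @export
rig_write <- function(rig, path) {
  dump <- function(cam) {
    list(
      id = cam$id, fx = cam$fx, fy = cam$fy, cx = cam$cx, cy = cam$cy,
      width = cam$width, height = cam$height,
      rotation = as.numeric(t(cam$R)), translation = as.numeric(cam$t)
    )
  }
  yaml::write_yaml(
    list(
      cameras = list(dump(rig$a), dump(rig$b)),
      separation = rig$separation, height = rig$height,
      subject_distance = rig$subject_distance
    ),
    path,
    precision = 15 # keep rotations orthonormal to the model's tolerance
  )
  invisible(path)
}
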