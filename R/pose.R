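#' Six-degree-of-freedom pose
#'
#' The pose vector optimized by the registration: three rotations in degrees
#' and three translations in millimetres, applied about a fixed rotation
#' center. Angles use the fixed-axis X -> Y -> Z (right-handed) convention;
#' storing angles in degrees lets one difference-spacing schedule cover both
#' "millimetres or degrees".
#'
#' @param rx,ry,rz rotations about the world x, y, z axes, degrees.
#' @param tx,ty,tz translations, mm.
#' @param rotation_center length-3 point (mm) the rotations pivot about;
#'   fixed for a whole registration.
#' @return object of class `pose6`.
#' @export
pose6 <- function(rx = 0, ry = 0, rz = 0, tx = 0, ty = 0, tz = 0,
                  rotation_center = c(0, 0, 0)) {
  v <- c(rx = rx, ry = ry, rz = rz, tx = tx, ty = ty, tz = tz)
  stopifnot(all(is.finite(v)), length(rotation_center) == 3L,
            all(is.finite(rotation_center)))
  structure(list(params = v, rotation_center = as.numeric(rotation_center)),
            class = "pose6")
}

#' @export
print.pose6 <- function(x, ...) {
  cat(sprintf("<pose6> r = (%.4g, %.4g, %.4g) deg, t = (%.4g, %.4g, %.4g) mm\n",
              x$params[1], x$params[2], x$params[3],
              x$params[4], x$params[5], x$params[6]))
  cat(sprintf("  rotation center (%.4g, %.4g, %.4g) mm\n",
              x$rotation_center[1], x$rotation_center[2], x$rotation_center[3]))
  invisible(x)
}

#' Extract or replace the six free pose parameters
#'
#' `pose_params()` returns the named vector (rx, ry, rz, tx, ty, tz);
#' `pose_with_params()` returns a copy of the pose with the parameters
#' replaced, keeping the rotation center.
#'
#' @param pose a [pose6()].
#' @param params numeric vector of length 6.
#' @return a named numeric vector, or a [pose6()].
#' @export
pose_params <- function(pose) pose$params

#' @rdname pose_params
#' @export
pose_with_params <- function(pose, params) {
  pose$params[] <- params
  pose
}

rot_x <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3L, 3L)
}
rot_y <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3L, 3L)
}
rot_z <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3L, 3L)
}

#' Convert a pose to its rigid transform
#'
#' Rotates about the pose's rotation center by fixed-axis X -> Y -> Z Euler
#' angles (R = Rz Ry Rx, degrees), then translates by (tx, ty, tz).
#'
#' @param pose a [pose6()].
#' @return a [rigid_transform()].
#' @export
pose_to_transform <- function(pose) {
  p <- pose$params
  ang <- p[1:3] * pi / 180
  r <- rot_z(ang[3]) %*% rot_y(ang[2]) %*% rot_x(ang[1])
  cen <- pose$rotation_center
  rigid_transform(r, cen - drop(r %*% cen) + p[4:6])
}

#' Recover a pose from a rigid transform
#'
#' Inverse of [pose_to_transform()] for the given rotation center. The Euler
#' extraction takes the |ry| <= 90 deg branch.
#'
#' @param tf a [rigid_transform()].
#' @param rotation_center length-3 center (mm) the pose should pivot about.
#' @return a [pose6()].
#' @export
transform_to_pose <- function(tf, rotation_center = c(0, 0, 0)) {
  r <- tf$rotation
  ry <- asin(max(-1, min(1, -r[3, 1])))
  if (abs(cos(ry)) > 1e-9) {
    rx <- atan2(r[3, 2], r[3, 3])
    rz <- atan2(r[2, 1], r[1, 1])
  } else {  # gimbal lock: fold rz into rx
    rx <- atan2(-r[2, 3], r[2, 2])
    rz <- 0
  }
  cen <- rotation_center
  t6 <- tf$translation - cen + drop(r %*% cen)
  pose6(rx * 180 / pi, ry * 180 / pi, rz * 180 / pi,
        t6[1], t6[2], t6[3], rotation_center = cen)
}

#' Per-axis absolute pose differences
#'
#' Absolute differences of the six pose parameters: rotations in degrees,
#' translations in mm. Both poses must share the rotation center, otherwise
#' the parameters are not comparable.
#'
#' @param a,b [pose6()]s with identical rotation centers.
#' @return named numeric vector `(rx, ry, rz, tx, ty, tz)` of absolute errors.
#' @export
pose_error <- function(a, b) {
  if (max(abs(a$rotation_center - b$rotation_center)) > 1e-9)
    stop("pose_error requires identical rotation centers")
  abs(a$params - b$params)
}
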