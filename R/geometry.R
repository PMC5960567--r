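#' Projection model for one radiographic view
#'
#' A 3x4 homogeneous projection matrix (11-DOF direct linear transformation,
#' DLT) mapping world coordinates in millimetres to continuous image pixel
#' coordinates, together with the raster dimensions and the physical pixel
#' spacing. Image coordinates are 0-based with the origin at the top-left
#' pixel center, x right, y down.
#'
#' @param matrix 3x4 numeric matrix, defined up to scale, rank 3.
#' @param image_width,image_height raster dimensions in pixels.
#' @param pixel_spacing physical detector pixel size, mm/px.
#' @return An object of class `projection_model`.
#' @export
projection_model <- function(matrix, image_width, image_height, pixel_spacing) {
  matrix <- as.matrix(matrix)
  stopifnot(identical(dim(matrix), c(3L, 4L)), all(is.finite(matrix)))
  if (qr(matrix)$rank < 3L) stop("projection matrix must have rank 3")
  structure(
    list(matrix = matrix,
         image_width = as.integer(image_width),
         image_height = as.integer(image_height),
         pixel_spacing = as.numeric(pixel_spacing)),
    class = "projection_model")
}

#' @export
print.projection_model <- function(x, ...) {
  cat(sprintf("<projection_model> %d x %d px, %.4g mm/px\n",
              x$image_width, x$image_height, x$pixel_spacing))
  print(signif(x$matrix / x$matrix[3, 4], 6))
  invisible(x)
}

#' The 11 DLT parameters of a projection model
#'
#' Rescales the 3x4 matrix so its last element equals 1 and returns the
#' remaining 11 entries row-major.
#' @param camera a [projection_model()].
#' @return numeric vector of length 11.
#' @export
dlt_parameters <- function(camera) {
  m <- camera$matrix / camera$matrix[3, 4]
  as.vector(t(m))[1:11]
}

#' Project a 3D point into image pixels
#'
#' Homogeneous multiply followed by the perspective divide. Points may project
#' outside the raster bounds; coordinates stay continuous.
#'
#' @param camera a [projection_model()].
#' @param p numeric vector of length 3 (mm), or an n x 3 matrix of points.
#' @return numeric length-2 vector (px), or an n x 2 matrix.
#' @export
project <- function(camera, p) {
  single <- is.null(dim(p))
  pts <- if (single) matrix(as.numeric(p), nrow = 1L) else as.matrix(p)
  stopifnot(ncol(pts) == 3L, all(is.finite(pts)))
  h <- pts %*% t(camera$matrix[, 1:3, drop = FALSE])
  h <- sweep(h, 2L, -camera$matrix[, 4], `-`)
  depth <- h[, 3]
  if (any(depth <= 0)) stop("point at non-positive depth (behind the camera)")
  out <- h[, 1:2, drop = FALSE] / depth
  colnames(out) <- c("x", "y")
  if (single) drop(out) else out
}

# depths along the principal axis (positive in front of the camera); used by
# the renderer to reject unrenderable poses
projection_depths <- function(camera, pts) {
  drop(pts %*% camera$matrix[3, 1:3] + camera$matrix[3, 4])
}

#' Marker set constructor
#'
#' A labelled set of 3D fiducial positions (tantalum beads) in millimetres,
#' stored as a tibble with columns `label`, `x`, `y`, `z`.
#'
#' @param xyz n x 3 numeric matrix of positions (mm).
#' @param label optional character labels; defaults to `m1`, `m2`, ...
#' @return tibble of class `marker_set`.
#' @export
marker_set <- function(xyz, label = NULL) {
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3L, all(is.finite(xyz)))
  if (is.null(label)) label <- paste0("m", seq_len(nrow(xyz)))
  out <- tibble::tibble(label = as.character(label),
                        x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  class(out) <- c("marker_set", class(out))
  out
}

marker_xyz <- function(markers) {
  as.matrix(markers[, c("x", "y", "z")])
}

# Hartley-style similarity normalization: centroid to origin, mean distance
# sqrt(d). Returns the (d+1)x(d+1) homogeneous transform.
normalize_points <- function(pts) {
  d <- ncol(pts)
  ctr <- colMeans(pts)
  centered <- sweep(pts, 2L, ctr)
  scale <- sqrt(d) / mean(sqrt(rowSums(centered^2)))
  if (!is.finite(scale)) scale <- 1
  t_mat <- diag(d + 1L)
  t_mat[seq_len(d), seq_len(d)] <- diag(scale, d)
  t_mat[seq_len(d), d + 1L] <- -scale * ctr
  t_mat
}

#' DLT camera calibration from bead correspondences
#'
#' Solves the 3x4 projection matrix from >= 6 world/image correspondences by
#' the direct linear transformation: the homogeneous linear system is solved
#' by the smallest right singular vector after Hartley point normalization of
#' both point sets. The recovered matrix is rescaled so calibration points
#' have positive depth.
#'
#' @param world_points a [marker_set()] (or n x 3 matrix) of bead positions, mm.
#' @param image_points n x 2 matrix (or data frame) of detected bead centers, px.
#' @param image_width,image_height,pixel_spacing raster metadata for the
#'   resulting model.
#' @return a [projection_model()] with attribute `rms` (reprojection RMS, px).
#' @export
dlt_calibrate <- function(world_points, image_points,
                          image_width = NA_integer_, image_height = NA_integer_,
                          pixel_spacing = NA_real_) {
  xyz <- if (inherits(world_points, "marker_set")) marker_xyz(world_points)
         else as.matrix(world_points)
  uv <- as.matrix(image_points)
  if (nrow(xyz) != nrow(uv)) stop("correspondence counts differ")
  n <- nrow(xyz)
  if (n < 6L) stop("calibration requires at least 6 correspondences")
  sv <- svd(sweep(xyz, 2L, colMeans(xyz)))$d
  if (sv[3] < 1e-8 * sv[1]) stop("degenerate calibration: world points are coplanar")

  t3 <- normalize_points(xyz)
  t2 <- normalize_points(uv)
  xh <- cbind(xyz, 1) %*% t(t3)
  uh <- cbind(uv, 1) %*% t(t2)

  a <- matrix(0, 2L * n, 12L)
  for (i in seq_len(n)) {
    xi <- xh[i, ]
    a[2L * i - 1L, ] <- c(xi, 0, 0, 0, 0, -uh[i, 1] * xi)
    a[2L * i, ]      <- c(0, 0, 0, 0, xi, -uh[i, 2] * xi)
  }
  v <- svd(a, nu = 0L)$v
  p_norm <- matrix(v[, 12L], 3L, 4L, byrow = TRUE)
  p <- solve(t2) %*% p_norm %*% t3

  depths <- drop(cbind(xyz, 1) %*% p[3, ])
  if (all(depths < 0)) p <- -p
  else if (any(depths == 0) || !all(sign(depths) == sign(depths[1])))
    stop("degenerate calibration: inconsistent point depths")
  p <- p / sqrt(sum(p[3, 1:3]^2))

  model <- projection_model(p, image_width, image_height, pixel_spacing)
  reproj <- project(model, xyz)
  attr(model, "rms") <- sqrt(mean(rowSums((reproj - uv)^2)))
  model
}

#' Linear (DLT) triangulation of a stereo correspondence
#'
#' Recovers the 3D position whose projections best match the two observed
#' pixel coordinates in the algebraic least-squares sense, via the smallest
#' singular vector of the stacked 4x4 homogeneous system.
#'
#' @param cam_a,cam_b [projection_model()]s of the two views.
#' @param x_a,x_b length-2 pixel coordinates of the correspondence.
#' @return numeric length-3 point (mm) with attribute `residual`, the mean
#'   reprojection distance in px.
#' @export
triangulate <- function(cam_a, cam_b, x_a, x_b) {
  ray_dir <- function(cam, uv) {
    d <- solve(cam$matrix[, 1:3], c(uv, 1))
    d / sqrt(sum(d^2))
  }
  da <- ray_dir(cam_a, x_a)
  db <- ray_dir(cam_b, x_b)
  if (abs(abs(sum(da * db)) - 1) < 1e-9)
    stop("degenerate triangulation: viewing rays are (near-)parallel")

  rows <- function(cam, uv) {
    p <- cam$matrix
    rbind(uv[1] * p[3, ] - p[1, ],
          uv[2] * p[3, ] - p[2, ])
  }
  a <- rbind(rows(cam_a, x_a), rows(cam_b, x_b))
  v <- svd(a, nu = 0L)$v[, 4L]
  if (abs(v[4]) < 1e-14) stop("triangulated point at infinity")
  pt <- v[1:3] / v[4]
  res <- mean(c(sqrt(sum((project(cam_a, pt) - x_a)^2)),
                sqrt(sum((project(cam_b, pt) - x_b)^2))))
  structure(pt, residual = res)
}

#' Least-squares rigid fit between two corresponded marker sets
#'
#' Orthogonal Procrustes (Kabsch) solution with the proper-rotation
#' correction, so the returned rotation always has determinant +1.
#'
#' @param src,dst [marker_set()]s (or n x 3 matrices) with corresponding rows.
#' @return a [rigid_transform()] with attribute `rmsd` (mm).
#' @export
rigid_fit <- function(src, dst) {
  a <- if (inherits(src, "marker_set")) marker_xyz(src) else as.matrix(src)
  b <- if (inherits(dst, "marker_set")) marker_xyz(dst) else as.matrix(dst)
  stopifnot(nrow(a) == nrow(b))
  if (nrow(a) < 3L) stop("rigid fit requires at least 3 points")
  ca <- colMeans(a); cb <- colMeans(b)
  aa <- sweep(a, 2L, ca); bb <- sweep(b, 2L, cb)
  if (svd(aa)$d[2] < 1e-9 * max(svd(aa)$d[1], 1))
    stop("rigid fit requires non-collinear points")
  s <- svd(t(aa) %*% bb)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  trans <- cb - drop(rot %*% ca)
  fitted <- sweep(a %*% t(rot), 2L, -trans)
  out <- rigid_transform(rot, trans)
  attr(out, "rmsd") <- sqrt(mean(rowSums((fitted - b)^2)))
  out
}

#' Rigid transform constructor
#'
#' @param rotation 3x3 proper orthonormal matrix.
#' @param translation length-3 vector, mm.
#' @return object of class `rigid_transform`; use [apply_transform()] to map
#'   points and `%*%`-style composition via [compose_transforms()].
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(identical(dim(rotation), c(3L, 3L)))
  if (max(abs(t(rotation) %*% rotation - diag(3))) > 1e-6 ||
      det(rotation) < 0)
    stop("rotation must be proper orthonormal")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' Apply a rigid transform to points
#' @param tf a [rigid_transform()].
#' @param pts length-3 vector or n x 3 matrix (mm).
#' @return transformed points, same shape.
#' @export
apply_transform <- function(tf, pts) {
  single <- is.null(dim(pts))
  m <- if (single) matrix(pts, 1L) else as.matrix(pts)
  out <- sweep(m %*% t(tf$rotation), 2L, -tf$translation)
  if (single) drop(out) else out
}

#' Compose two rigid transforms (first `a`, then `b`)
#' @param b,a [rigid_transform()]s.
#' @return the composite [rigid_transform()].
#' @export
compose_transforms <- function(b, a) {
  rigid_transform(b$rotation %*% a$rotation,
                  drop(b$rotation %*% a$translation) + b$translation)
}

#' Invert a rigid transform
#' @param tf a [rigid_transform()].
#' @return the inverse [rigid_transform()].
#' @export
invert_transform <- function(tf) {
  rigid_transform(t(tf$rotation), drop(-t(tf$rotation) %*% tf$translation))
}
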