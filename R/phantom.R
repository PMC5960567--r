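# run expr under a local RNG seed, restoring the caller's RNG state
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Synthetic femoral-stem mesh
#'
#' A watertight stand-in for a reverse-engineered cementless stem: a lofted
#' surface of tapered, twisted, laterally bowed elliptical cross-sections
#' (about 135 mm of stem) capped at both ends, plus an off-axis sphere for
#' the ball head, about 155 mm tall overall. The lateral bow, the twist and
#' the off-axis head make the silhouette strongly asymmetric, which is the
#' property that makes pose recovery from two views possible; the seed
#' perturbs the section radii slightly so different seeds give distinct but
#' equally realistic implants.
#'
#' @param seed integer; the mesh is bit-identical for equal seeds.
#' @param n_segments number of points around each cross-section, >= 8.
#' @param n_sections number of cross-sections along the stem.
#' @return a [triangle_mesh()] with attribute `head_center` (mm), the ball
#'   head sphere center.
#' @export
make_stem_mesh <- function(seed = 1L, n_segments = 48L, n_sections = 56L) {
  stopifnot(n_segments >= 8L, n_sections >= 4L)
  # seed-controlled low-order harmonic perturbation of the radius profiles:
  # smooth in arc length, so the surface converges to the same shape as the
  # discretization is refined
  coef <- with_local_seed(seed, matrix(stats::runif(6, -1, 1), 2L))
  y <- seq(-105, 30, length.out = n_sections)
  s <- (y + 105) / 135
  wobble <- function(cf) 1 + 0.02 * (cf[1] * cos(2 * pi * s) +
                                     cf[2] * sin(2 * pi * s) +
                                     cf[3] * cos(4 * pi * s))
  a <- (3 + 10 * s^1.2) * wobble(coef[1, ])   # medial-lateral half axis, mm
  b <- (2.5 + 6.5 * s) * wobble(coef[2, ])    # antero-posterior half axis, mm
  cx <- 9 * s^2                           # lateral bow
  cz <- 2 * s^1.5
  twist <- 18 * s * pi / 180              # proximodistal twist, rad

  # superelliptical (rounded-rectangular) cross-section: cementless revision
  # stems of this type have a rectangular tapered profile, and the corners
  # are what makes the silhouette sensitive to proximodistal rotation
  th <- 2 * pi * (seq_len(n_segments) - 1L) / n_segments
  se <- function(u) sign(u) * abs(u)^(2 / 6)
  rings <- vector("list", n_sections)
  for (i in seq_len(n_sections)) {
    ex <- a[i] * se(cos(th)); ez <- b[i] * se(sin(th))
    ct <- cos(twist[i]); st <- sin(twist[i])
    rings[[i]] <- cbind(cx[i] + ct * ex + st * ez,
                        y[i],
                        cz[i] - st * ex + ct * ez)
  }
  verts <- do.call(rbind, rings)
  faces <- list()
  idx <- function(i, k) (i - 1L) * n_segments + ((k - 1L) %% n_segments) + 1L
  for (i in seq_len(n_sections - 1L)) {
    for (k in seq_len(n_segments)) {
      v00 <- idx(i, k); v01 <- idx(i, k + 1L)
      v10 <- idx(i + 1L, k); v11 <- idx(i + 1L, k + 1L)
      faces[[length(faces) + 1L]] <- c(v00, v10, v11)
      faces[[length(faces) + 1L]] <- c(v00, v11, v01)
    }
  }
  # end caps: triangle fans from the ring centroids
  cbot <- nrow(verts) + 1L
  verts <- rbind(verts, c(cx[1], y[1], cz[1]))
  for (k in seq_len(n_segments))
    faces[[length(faces) + 1L]] <- c(cbot, idx(1L, k + 1L), idx(1L, k))
  ctop <- nrow(verts) + 1L
  verts <- rbind(verts, c(cx[n_sections], y[n_sections], cz[n_sections]))
  for (k in seq_len(n_segments))
    faces[[length(faces) + 1L]] <- c(ctop, idx(n_sections, k),
                                     idx(n_sections, k + 1L))

  # ball head: UV sphere, off-axis both medially and anteriorly
  head_center <- c(cx[n_sections] + 6, 38, 4)
  head_r <- 14
  n_lat <- max(6L, n_segments %/% 2L)
  sph_v <- list(head_center + c(0, head_r, 0))
  for (i in seq_len(n_lat - 1L)) {
    phi <- pi * i / n_lat
    for (k in seq_len(n_segments)) {
      lam <- 2 * pi * (k - 1L) / n_segments
      sph_v[[length(sph_v) + 1L]] <-
        head_center + head_r * c(sin(phi) * cos(lam), cos(phi),
                                 sin(phi) * sin(lam))
    }
  }
  sph_v[[length(sph_v) + 1L]] <- head_center + c(0, -head_r, 0)
  off <- nrow(verts)
  verts <- rbind(verts, do.call(rbind, sph_v))
  spi <- function(i, k) off + 1L + (i - 1L) * n_segments +
    ((k - 1L) %% n_segments) + 1L
  south <- off + 1L + (n_lat - 1L) * n_segments + 1L
  for (k in seq_len(n_segments))
    faces[[length(faces) + 1L]] <- c(off + 1L, spi(1L, k + 1L), spi(1L, k))
  for (i in seq_len(n_lat - 2L)) {
    for (k in seq_len(n_segments)) {
      faces[[length(faces) + 1L]] <- c(spi(i, k), spi(i, k + 1L),
                                       spi(i + 1L, k + 1L))
      faces[[length(faces) + 1L]] <- c(spi(i, k), spi(i + 1L, k + 1L),
                                       spi(i + 1L, k))
    }
  }
  for (k in seq_len(n_segments))
    faces[[length(faces) + 1L]] <- c(south, spi(n_lat - 1L, k),
                                     spi(n_lat - 1L, k + 1L))

  mesh <- triangle_mesh(verts, do.call(rbind, faces))
  attr(mesh, "head_center") <- head_center
  mesh
}

#' Biplanar stereo rig with calibration cage
#'
#' Two pinhole projection models whose principal rays intersect at the scene
#' origin with the given angle between them (rotation about the proximodistal
#' y axis), plus a 36-bead calibration cage on two parallel planes with exact
#' per-view 2D projections. Calibrating from the bead correspondences with
#' [dlt_calibrate()] recovers each camera.
#'
#' @param angle_deg angle between the two viewing directions, 20-160 degrees.
#' @param source_distance_mm source-to-origin distance (default 1000 mm).
#' @param pixel_spacing detector pixel size, mm/px.
#' @param image_size raster side length in px; default covers a ~300 mm
#'   field of view at the given spacing.
#' @param sdd_mm source-to-detector distance (default 1100 mm, so the
#'   magnification at the origin is 1.1).
#' @return list with `ap` and `lat` [projection_model()]s, `cage`
#'   ([marker_set()], mm) and `cage_image` (per-view n x 2 pixel matrices).
#' @export
make_stereo_rig <- function(angle_deg = 90, source_distance_mm = 1000,
                            pixel_spacing = 0.5, image_size = NULL,
                            sdd_mm = 1100) {
  if (angle_deg < 20 || angle_deg > 160)
    stop("degenerate stereo angle: must be within [20, 160] degrees")
  if (is.null(image_size)) image_size <- as.integer(round(300 / pixel_spacing))
  f <- sdd_mm / pixel_spacing
  ccx <- (image_size - 1) / 2
  k <- matrix(c(f, 0, 0, 0, f, 0, ccx, ccx, 1), 3L, 3L)

  build <- function(rot_world) {
    src <- drop(rot_world %*% c(0, 0, source_distance_mm))
    xc <- drop(rot_world %*% c(1, 0, 0))
    yc <- c(0, -1, 0)
    zc <- drop(rot_world %*% c(0, 0, -1))
    rc <- rbind(xc, yc, zc)
    p <- k %*% cbind(rc, -drop(rc %*% src))
    projection_model(p, image_size, image_size, pixel_spacing)
  }
  ap <- build(diag(3))
  lat <- build(rot_y(angle_deg * pi / 180))

  gx <- seq(-90, 90, length.out = 6L)
  gy <- c(-110, 0, 110)
  grid <- as.matrix(expand.grid(x = gx, y = gy))
  cage <- marker_set(rbind(cbind(grid, z = 110), cbind(grid, z = -110)),
                     label = paste0("cage", 1:36))
  list(ap = ap, lat = lat, cage = cage,
       cage_image = list(ap = project(ap, marker_xyz(cage)),
                         lat = project(lat, marker_xyz(cage))))
}

#' Synthetic phantom scene
#'
#' Bundles everything the in silico evaluation needs: the stem mesh, its
#' ground-truth pose (the identity pose about the mesh centroid), the stereo
#' rig with calibration cage, and ten phantom fiducial beads with a known
#' rigid relation to the implant. Deterministic given the seed.
#'
#' @param seed integer seed for the mesh and bead placement.
#' @param pixel_spacing detector pixel size, mm/px.
#' @param angle_deg stereo angle, degrees.
#' @param n_segments,n_sections stem mesh resolution (points per cross-section,
#'   cross-sections along the stem).
#' @param ... further arguments to [make_stereo_rig()].
#' @return object of class `phantom_scene`.
#' @export
phantom_scene <- function(seed = 1L, pixel_spacing = 0.5, angle_deg = 90,
                          n_segments = 48L, n_sections = 56L, ...) {
  mesh <- make_stem_mesh(seed, n_segments = n_segments,
                         n_sections = n_sections)
  rig <- make_stereo_rig(angle_deg = angle_deg,
                         pixel_spacing = pixel_spacing, ...)
  beads <- with_local_seed(seed + 1000L,
    cbind(runif(10, -45, 45), runif(10, -95, 35), runif(10, -25, 25)))
  structure(
    list(mesh = mesh,
         ground_truth_pose = pose6(rotation_center = mesh_centroid(mesh)),
         cameras = list(ap = rig$ap, lat = rig$lat),
         cage_markers = rig$cage,
         cage_image = rig$cage_image,
         phantom_markers = marker_set(beads, paste0("bead", 1:10)),
         pixel_spacing = pixel_spacing,
         seed = as.integer(seed)),
    class = "phantom_scene")
}

#' @export
print.phantom_scene <- function(x, ...) {
  cat(sprintf("<phantom_scene> seed %d, %.4g mm/px, %d x %d px per view\n",
              x$seed, x$pixel_spacing,
              x$cameras$ap$image_width, x$cameras$ap$image_height))
  print(x$mesh)
  invisible(x)
}

#' Simulate a radiograph of the phantom scene
#'
#' Binary mode returns the exact silhouette at the ground-truth pose.
#' Grayscale mode emulates a high-contrast enhanced radiograph of a highly
#' radiopaque implant: foreground pixels ~ N(0.95, sigma), background
#' ~ N(0.2, sigma), clipped to [0, 1].
#'
#' @param scene a [phantom_scene()].
#' @param view `"ap"` or `"lat"`.
#' @param mode `"binary"` or `"grayscale"`.
#' @param noise_sigma Gaussian intensity noise SD (grayscale mode).
#' @param seed seed for the noise; deterministic given the seed.
#' @return a [radiograph()].
#' @export
simulate_radiograph <- function(scene, view = c("ap", "lat"),
                                mode = c("binary", "grayscale"),
                                noise_sigma = 0.05, seed = 1L) {
  view <- match.arg(view)
  mode <- match.arg(mode)
  cam <- scene$cameras[[view]]
  sil <- render_silhouette(scene$mesh, cam, scene$ground_truth_pose)
  if (mode == "binary")
    return(radiograph(matrix(as.numeric(sil), nrow(sil)),
                      scene$pixel_spacing, is_binary = TRUE))
  base <- ifelse(unclass(sil) == 1L, 0.95, 0.2)
  img <- with_local_seed(seed,
    base + matrix(stats::rnorm(length(base), 0, noise_sigma), nrow(base)))
  radiograph(pmin(pmax(img, 0), 1), scene$pixel_spacing, is_binary = FALSE)
}

#' Sample random initial poses around a ground truth
#'
#' Each of the six degrees of freedom is offset by an independent
#' Uniform(-bound, +bound) draw, matching the in silico protocol of limiting
#' maximal translational and rotational initial errors.
#'
#' @param truth the ground-truth [pose6()].
#' @param bound maximal absolute offset, mm and degrees; >= 0.
#' @param n number of poses.
#' @param seed RNG seed; the list is reproducible given the seed.
#' @return list of `n` [pose6()]s sharing the truth's rotation center.
#' @export
sample_initial_poses <- function(truth, bound, n, seed = 1L) {
  stopifnot(bound >= 0, n >= 1)
  offs <- with_local_seed(seed,
    matrix(stats::runif(6L * n, -bound, bound), nrow = n))
  lapply(seq_len(n), function(i)
    pose_with_params(truth, pose_params(truth) + offs[i, ]))
}

#' Drop-out scenario around the ball head
#'
#' Builds one circular drop-out mask per view, centered on the projected
#' ball-head center, with the radius chosen (by bisection) so the mask
#' covers approximately `fraction` of the silhouette's lit area. Optionally
#' burns a bright occluder disk (an acetabular-cup stand-in at intensity
#' 0.95) into supplied grayscale radiographs; the occluder is offset from
#' the head center so it corrupts the silhouette boundary, and the masks are
#' enlarged to cover it.
#'
#' @param scene a [phantom_scene()].
#' @param fraction target masked fraction of the lit area, in (0, 0.5).
#' @param radiographs optional named list (`ap`, `lat`) of grayscale
#'   [radiograph()]s to burn the occluder into.
#' @return list with `masks` (named list of logical matrices) and, when
#'   `radiographs` is given, `radiographs` (occluded copies) and
#'   `occluder_centers`.
#' @export
make_dropout_scenario <- function(scene, fraction = 0.15,
                                  radiographs = NULL) {
  stopifnot(fraction > 0, fraction < 0.5)
  head3 <- attr(scene$mesh, "head_center")
  tf <- pose_to_transform(scene$ground_truth_pose)
  head3 <- apply_transform(tf, head3)
  out_masks <- list()
  out_radio <- list()
  centers <- list()
  for (view in c("ap", "lat")) {
    cam <- scene$cameras[[view]]
    sil <- unclass(render_silhouette(scene$mesh, cam,
                                     scene$ground_truth_pose))
    lit <- sum(sil)
    ctr <- project(cam, head3)
    colg <- matrix(seq_len(ncol(sil)) - 1L, nrow(sil), ncol(sil), byrow = TRUE)
    rowg <- matrix(seq_len(nrow(sil)) - 1L, nrow(sil), ncol(sil))
    d2 <- (colg - ctr[1])^2 + (rowg - ctr[2])^2
    target <- fraction * lit
    lo <- 0; hi <- max(dim(sil))
    for (i in 1:40) {
      mid <- (lo + hi) / 2
      cov <- sum(sil == 1L & d2 <= mid^2)
      if (cov < target) lo <- mid else hi <- mid
    }
    r <- (lo + hi) / 2
    if (is.null(radiographs)) {
      out_masks[[view]] <- d2 <= r^2
    } else {
      occ_ctr <- ctr + c(0.6 * r, -0.2 * r)
      d2o <- (colg - occ_ctr[1])^2 + (rowg - occ_ctr[2])^2
      occ <- d2o <= r^2
      img <- radiographs[[view]]
      if (img$is_binary) stop("occluder burning requires grayscale radiographs")
      m <- img$intensity
      m[occ] <- pmin(1, 0.95 + (m[occ] - mean(m[occ])) * 0)
      out_radio[[view]] <- radiograph(m, img$pixel_spacing, is_binary = FALSE)
      out_masks[[view]] <- d2o <= (r + 3)^2
      centers[[view]] <- occ_ctr
    }
  }
  out <- list(masks = out_masks)
  if (!is.null(radiographs)) {
    out$radiographs <- out_radio
    out$occluder_centers <- centers
  }
  out
}
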