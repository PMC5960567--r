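test_that("DLT calibration recovers the generating camera from cage beads", {
  rig <- make_stereo_rig(angle_deg = 90, pixel_spacing = 0.5)
  for (v in c("ap", "lat")) {
    p0 <- rig[[v]]
    fit <- dlt_calibrate(rig$cage, rig$cage_image[[v]],
                         p0$image_width, p0$image_height, p0$pixel_spacing)
    expect_lt(attr(fit, "rms"), 1e-8)
    # matrices agree up to scale (both rows-3 normalized to unit norm)
    n0 <- p0$matrix / sqrt(sum(p0$matrix[3, 1:3]^2))
    nf <- fit$matrix * sign(sum(fit$matrix * n0))
    expect_lt(max(abs(nf - n0)), 1e-8)
  }
})

test_that("DLT on a canonical identity camera reprojects identically", {
  p0 <- projection_model(cbind(diag(3), 0), 10L, 10L, 1)
  set.seed(3)
  pts <- cbind(runif(12, -1, 1), runif(12, -1, 1), runif(12, 2, 5))
  uv <- project(p0, pts)
  fit <- dlt_calibrate(pts, uv, 10L, 10L, 1)
  expect_lt(max(abs(project(fit, pts) - uv)), 1e-9)
})

test_that("DLT rejects underdetermined and degenerate configurations", {
  rig <- make_stereo_rig(pixel_spacing = 0.5)
  xyz <- marker_xyz <- as.matrix(rig$cage[, c("x", "y", "z")])
  uv <- rig$cage_image$ap
  expect_error(dlt_calibrate(xyz[1:5, ], uv[1:5, ]), "at least 6")
  flat <- xyz; flat[, 3] <- 0
  expect_error(dlt_calibrate(flat, uv), "coplanar")
})

test_that("projection performs the homogeneous multiply and divide", {
  p0 <- projection_model(cbind(diag(3), 0), 10L, 10L, 1)
  expect_equal(unname(project(p0, c(0, 0, 1))), c(0, 0))
  expect_equal(unname(project(p0, c(1, 1, 2))), c(0.5, 0.5))
  expect_error(project(p0, c(0, 0, -1)), "depth")

  m <- matrix(c(2.5, -1, 0.3, 4,
                0.1, 3, -0.7, 1,
                0.01, 0.02, 1, 0.5), 3L, 4L, byrow = TRUE)
  cam <- projection_model(m, 10L, 10L, 1)
  x <- c(3, -2, 7)
  h <- m %*% c(x, 1)
  expect_equal(unname(project(cam, x)), c(h[1] / h[3], h[2] / h[3]))
})

test_that("triangulation inverts projection and degrades gracefully with noise", {
  rig <- make_stereo_rig(angle_deg = 90, pixel_spacing = 0.5)
  pt <- c(12, -35, 8)
  tri <- triangulate(rig$ap, rig$lat, project(rig$ap, pt), project(rig$lat, pt))
  expect_lt(max(abs(tri - pt)), 1e-9)
  expect_lt(attr(tri, "residual"), 1e-9)

  # Monte-Carlo bound under 0.1 px Gaussian pixel noise
  set.seed(11)
  errs <- replicate(100, {
    p <- c(runif(1, -40, 40), runif(1, -80, 30), runif(1, -20, 20))
    ua <- project(rig$ap, p) + rnorm(2, 0, 0.1)
    ul <- project(rig$lat, p) + rnorm(2, 0, 0.1)
    sqrt(sum((triangulate(rig$ap, rig$lat, ua, ul) - p)^2))
  })
  expect_lt(max(errs), 5 * rig$ap$pixel_spacing)
})

test_that("triangulation with identical cameras is flagged degenerate", {
  rig <- make_stereo_rig(pixel_spacing = 0.5)
  expect_error(triangulate(rig$ap, rig$ap, c(100, 100), c(100, 100)),
               "parallel")
})

test_that("rigid fit recovers known transforms with a proper rotation", {
  set.seed(5)
  src <- matrix(runif(30, -50, 50), 10L)
  fit0 <- rigid_fit(src, src)
  expect_lt(max(abs(fit0$rotation - diag(3))), 1e-12)
  expect_lt(attr(fit0, "rmsd"), 1e-12)

  rot <- rot_z_deg <- pose_to_transform(pose6(rz = 30))$rotation
  dst <- sweep(src %*% t(rot), 2L, -c(4, -7, 2))
  fit <- rigid_fit(src, dst)
  expect_lt(max(abs(fit$rotation - rot)), 1e-9)
  expect_lt(max(abs(fit$translation - c(4, -7, 2))), 1e-9)

  # reflection-only correspondence still yields det +1
  mirrored <- src %*% diag(c(-1, 1, 1))
  fitm <- rigid_fit(src, mirrored)
  expect_equal(det(fitm$rotation), 1, tolerance = 1e-12)

  expect_error(rigid_fit(src[1:2, ], dst[1:2, ]), "3 points")
  line <- cbind(1:5, 2 * (1:5), -(1:5))
  expect_error(rigid_fit(line, line), "collinear")
})

test_that("rigid-fit RMSD is invariant to a common rigid pre-transform", {
  set.seed(9)
  src <- matrix(runif(30, -50, 50), 10L)
  dst <- src + matrix(rnorm(30, 0, 0.5), 10L)
  base <- attr(rigid_fit(src, dst), "rmsd")
  pre <- pose_to_transform(pose6(17, -40, 8, 5, -3, 12))
  moved <- attr(rigid_fit(apply_transform(pre, src),
                          apply_transform(pre, dst)), "rmsd")
  expect_equal(moved, base, tolerance = 1e-9)
})

test_that("pose-to-transform follows the fixed-axis X-Y-Z convention", {
  expect_lt(max(abs(pose_to_transform(pose6())$rotation - diag(3))), 1e-15)
  expect_equal(pose_to_transform(pose6())$translation, c(0, 0, 0))
  # right-handed quarter turn about x maps +y to +z
  tf <- pose_to_transform(pose6(rx = 90))
  expect_lt(max(abs(apply_transform(tf, c(0, 1, 0)) - c(0, 0, 1))), 1e-12)
})

test_that("pose round-trips through its rigid transform", {
  set.seed(21)
  for (i in 1:20) {
    cen <- runif(3, -30, 30)
    p <- pose6(runif(1, -80, 80), runif(1, -80, 80), runif(1, -80, 80),
               runif(1, -20, 20), runif(1, -20, 20), runif(1, -20, 20),
               rotation_center = cen)
    back <- transform_to_pose(pose_to_transform(p), rotation_center = cen)
    expect_pose_equal(back, p, tol = 1e-10)
  }
})

test_that("pure translations compose additively", {
  t1 <- pose_to_transform(pose6(tx = 1.5, ty = -2, tz = 0.25))
  t2 <- pose_to_transform(pose6(tx = -0.5, ty = 4, tz = 1))
  both <- compose_transforms(t2, t1)
  direct <- pose_to_transform(pose6(tx = 1, ty = 2, tz = 1.25))
  expect_lt(max(abs(both$translation - direct$translation)), 1e-12)
  expect_lt(max(abs(both$rotation - diag(3))), 1e-15)
})

test_that("pose error reports per-axis absolute differences", {
  a <- pose6(1, 2, 3, 4, 5, 6)
  expect_equal(unname(pose_error(a, a)), rep(0, 6))
  b <- pose6(1, 2.5, 3, 4, 5, 6)
  expect_equal(unname(pose_error(a, b)), c(0, 0.5, 0, 0, 0, 0))
  # the worked silhouette-comparison example's stated perturbation magnitudes
  err <- pose_error(pose6(4.59, -3.68, -2.38, -1.31, 1.07, -1.03), pose6())
  expect_equal(unname(err), c(4.59, 3.68, 2.38, 1.31, 1.07, 1.03))
  expect_error(pose_error(a, pose6(rotation_center = c(1, 0, 0))),
               "rotation centers")
})
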