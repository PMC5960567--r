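# Shared fixtures: everything is generated in code at test time.

# small, fast phantom scene for unit tests (coarse detector)
tiny_scene <- function(seed = 1L, pixel_spacing = 1.0, ...) {
  phantom_scene(seed, pixel_spacing = pixel_spacing,
                n_segments = 16L, n_sections = 12L, ...)
}

scene_views <- function(scene, mode = "binary", masks = list(ap = NULL, lat = NULL),
                        noise_sigma = 0.05, seed = 7L) {
  dr <- list(
    ap = simulate_radiograph(scene, "ap", mode, noise_sigma, seed),
    lat = simulate_radiograph(scene, "lat", mode, noise_sigma, seed + 1L))
  list(list(dr = dr$ap, camera = scene$cameras$ap, mask = masks$ap),
       list(dr = dr$lat, camera = scene$cameras$lat, mask = masks$lat))
}

# independent point-in-triangle oracle (barycentric signs, inclusive edges)
oracle_point_in_tri <- function(px, py, tri) {
  s <- function(ax, ay, bx, by) (bx - ax) * (py - ay) - (by - ay) * (px - ax)
  d1 <- s(tri[1, 1], tri[1, 2], tri[2, 1], tri[2, 2])
  d2 <- s(tri[2, 1], tri[2, 2], tri[3, 1], tri[3, 2])
  d3 <- s(tri[3, 1], tri[3, 2], tri[1, 1], tri[1, 2])
  (d1 >= 0 && d2 >= 0 && d3 >= 0) || (d1 <= 0 && d2 <= 0 && d3 <= 0)
}

# brute-force NOA by an explicit double loop over pixels
oracle_noa_double_loop <- function(dr_mat, drr_mat, mask = NULL) {
  acc <- 0
  for (i in seq_len(nrow(dr_mat))) {
    for (j in seq_len(ncol(dr_mat))) {
      if (!is.null(mask) && mask[i, j]) next
      acc <- acc + (dr_mat[i, j] - drr_mat[i, j])^2
    }
  }
  acc
}

# simple pinhole camera with principal point at the raster center
test_camera <- function(f = 100, width = 64L, height = 64L, spacing = 1) {
  cx <- (width - 1) / 2
  p <- rbind(c(f, 0, cx, 0),
             c(0, f, cx, 0),
             c(0, 0, 1, 0))
  projection_model(p, width, height, spacing)
}

expect_pose_equal <- function(a, b, tol = 1e-8) {
  expect_lt(max(abs(pose_params(a) - pose_params(b))), tol)
}
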