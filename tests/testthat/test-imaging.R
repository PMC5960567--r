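test_that("histogram equalization is the CDF mapping", {
  # two-level image: 25% at the lower level -> CDF values 0.25 and 1
  img <- radiograph(matrix(c(rep(0.2, 4), rep(0.8, 12)), 4L), 1)
  eq <- equalize_histogram(img)
  expect_equal(sort(unique(as.vector(eq$intensity))), c(0.25, 1))
  expect_equal(eq$intensity[img$intensity == 0.2][1], 0.25)

  # uniform 256-level image is (nearly) a fixed point
  u <- matrix((rep(0:255, 4) + 0.5) / 256, 32L)
  equ <- equalize_histogram(radiograph(u, 1))
  expect_lt(max(abs(equ$intensity - u)), 1 / 256 + 1e-12)

  # constant image collapses to a constant
  const <- equalize_histogram(radiograph(matrix(0.37, 5L, 5L), 1))
  expect_equal(unique(as.vector(const$intensity)), 1)

  expect_error(equalize_histogram(radiograph(matrix(c(0, 1), 2L, 2L), 1)),
               "binary")
})

test_that("equalization is idempotent up to quantization and preserves order", {
  set.seed(4)
  img <- radiograph(matrix(runif(10000)^2, 100L), 1)
  once <- equalize_histogram(img)
  twice <- equalize_histogram(once)
  expect_lt(max(abs(twice$intensity - once$intensity)), 0.05)
  # monotone mapping preserves pixel ordering
  o <- order(img$intensity)
  expect_false(is.unsorted(once$intensity[o]))
})

test_that("threshold segmentation after equalization ignores monotone remaps", {
  # two well-separated intensity clusters (threshold away from bin edges):
  # any monotone remap preserves the rank structure, hence the segmentation
  set.seed(8)
  base <- matrix(ifelse(runif(2500) < 0.4, 0.8, 0.1), 50L)
  for (remap in list(function(x) x^3, sqrt, function(x) x / 2)) {
    a <- threshold_segment(equalize_histogram(radiograph(base, 1)), 0.5)
    b <- threshold_segment(equalize_histogram(radiograph(remap(base), 1)), 0.5)
    expect_identical(a$intensity, b$intensity)
  }
})

test_that("threshold segmentation thresholds as a fraction of range", {
  bin <- radiograph(matrix(c(0, 1, 1, 0), 2L), 1)
  expect_identical(threshold_segment(bin, 0.5)$intensity, bin$intensity)
  ramp <- radiograph(matrix(seq(0, 1, length.out = 100), 10L), 1)
  seg <- threshold_segment(ramp, 0.5)
  expect_equal(sum(seg$intensity), sum(ramp$intensity >= 0.5))
  expect_error(threshold_segment(ramp, 0), "threshold")
})

test_that("noisy synthetic radiograph segments to within half a percent", {
  scene <- tiny_scene(pixel_spacing = 0.5)
  truth <- unclass(render_silhouette(scene$mesh, scene$cameras$ap,
                                     scene$ground_truth_pose))
  gray <- simulate_radiograph(scene, "ap", "grayscale", noise_sigma = 0.05,
                              seed = 3L)
  seg <- threshold_segment(gray, 0.6)
  expect_lt(mean(seg$intensity != truth), 0.005)
})

test_that("ROI is the margin-expanded bounding box, clamped to the frame", {
  m <- matrix(0, 12L, 12L)
  m[6, 6] <- 1  # 0-based (5, 5)
  roi <- compute_roi(radiograph(m, 1, TRUE), 2L)
  expect_equal(unclass(roi)[c("x0", "y0", "width", "height")],
               list(x0 = 3L, y0 = 3L, width = 5L, height = 5L))

  full <- compute_roi(radiograph(matrix(1, 8L, 8L), 1, TRUE), 10L)
  expect_equal(c(full$x0, full$y0, full$width, full$height), c(0, 0, 8, 8))

  expect_error(compute_roi(radiograph(matrix(0, 4L, 4L), 1, TRUE), 1L),
               "empty segmentation")

  set.seed(2)
  sp <- matrix(rbinom(400, 1, 0.05), 20L)
  sp[3, 17] <- 1
  roi2 <- compute_roi(radiograph(sp, 1, TRUE), 1L)
  lit <- which(sp == 1, arr.ind = TRUE)
  expect_equal(roi2$x0, max(0L, min(lit[, 2]) - 2L))
  expect_equal(roi2$y0, max(0L, min(lit[, 1]) - 2L))
  expect_equal(roi2$x0 + roi2$width - 1L, min(19L, max(lit[, 2])))
  expect_equal(roi2$y0 + roi2$height - 1L, min(19L, max(lit[, 1])))
})

test_that("drop-out masks shrink the residual vector and can hide discord", {
  dr <- radiograph(matrix(rbinom(64, 1, 0.5), 8L), 1, TRUE)
  drr <- matrix(rbinom(64, 1, 0.5), 8L)
  none <- matrix(FALSE, 8L, 8L)
  expect_length(pixel_differences(dr, drr, mask = none), 64L)

  k_mask <- none; k_mask[2:3, 4:6] <- TRUE
  expect_length(pixel_differences(dr, drr, mask = k_mask), 64L - 6L)

  discord <- dr$intensity != drr
  expect_equal(noa(pixel_differences(dr, drr, mask = discord)), 0)

  expect_error(pixel_differences(dr, drr, mask = matrix(FALSE, 4L, 4L)),
               "dimensions")
})

test_that("radiograph and mask files round-trip through PNG and TIFF", {
  tmp <- withr::local_tempdir()
  set.seed(6)
  img <- radiograph(matrix(round(runif(120) * 255) / 255, 10L), 0.5)
  for (ext in c("png", "tif")) {
    p <- file.path(tmp, paste0("x.", ext))
    write_radiograph(img, p)
    back <- read_radiograph(p, 0.5)
    expect_equal(back$intensity, img$intensity, tolerance = 1 / 255)
  }
  mask <- matrix(c(TRUE, FALSE), 8L, 8L)
  mp <- file.path(tmp, "mask.png")
  write_mask(mask, mp)
  expect_identical(load_mask(mp), mask)
  expect_error(load_mask(mp, dim = c(4L, 4L)), "dimensions")
})

test_that("gamma adjustment is monotone and rejects binary input", {
  img <- radiograph(matrix(seq(0, 1, length.out = 16), 4L), 1)
  adj <- adjust_gamma(img, 2)
  expect_equal(adj$intensity, img$intensity^2)
  expect_error(adjust_gamma(threshold_segment(img, 0.5), 2), "binary")
})
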