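#' Pixel-difference residual vector
#'
#' The per-pixel difference DR - DRR between the real radiograph and the
#' rendered silhouette over the (optionally cropped and masked) region of
#' interest. Entries are ordered row-major within the ROI (y outer, x inner);
#' drop-out pixels are omitted, so the vector length shrinks accordingly.
#' For binary DR the entries lie in \{-1, 0, 1\}; for equalized grayscale DR
#' they are real values in [-1, 1].
#'
#' @param dr a [radiograph()].
#' @param drr a rendered silhouette (0/1 matrix) of the same full-frame
#'   dimensions and pixel spacing.
#' @param roi optional [compute_roi()] region; default full frame.
#' @param mask optional logical drop-out matrix (full frame), `TRUE` = excluded.
#' @return numeric residual vector.
#' @export
pixel_differences <- function(dr, drr, roi = NULL, mask = NULL) {
  drm <- unclass(drr)
  if (inherits(drr, "silhouette") &&
      !isTRUE(all.equal(attr(drr, "pixel_spacing"), dr$pixel_spacing)))
    stop("pixel spacings of DR and DRR differ")
  if (!identical(dim(dr$intensity), dim(drm)))
    stop("DR and DRR dimensions differ")
  if (!is.null(mask) && !identical(dim(mask), dim(drm)))
    stop("mask dimensions differ from the radiograph")
  a <- dr$intensity
  b <- drm
  if (!is.null(roi)) {
    a <- crop_roi(a, roi); b <- crop_roi(b, roi)
    if (!is.null(mask)) mask <- crop_roi(mask, roi)
  }
  res <- as.vector(t(a - b))
  if (!is.null(mask)) res <- res[!as.vector(t(mask))]
  res
}

#' Nonoverlapping area from a residual vector
#'
#' The sum of squared pixel differences. For binary segmentations this equals
#' the count of pixels where the real and reconstructed segmentations
#' disagree — the size of the nonoverlapping area.
#'
#' @param res a residual vector from [pixel_differences()].
#' @return non-negative scalar.
#' @export
noa <- function(res) sum(res^2)

#' Relative nonoverlapping area
#'
#' NOA / (NOA + C), where C is the count of unmasked pixels on which both
#' segmentations equal 1 (the overlap). Defined only for binary DR; it
#' normalizes away radiograph resolution and perspective scaling, so 0 means
#' identical silhouettes and 1 means no overlap at all.
#'
#' @inheritParams pixel_differences
#' @return fraction in [0, 1].
#' @export
relative_noa <- function(dr, drr, roi = NULL, mask = NULL) {
  if (!dr$is_binary)
    stop("relative NOA is undefined for grayscale radiographs")
  res <- pixel_differences(dr, drr, roi, mask)
  a <- dr$intensity
  b <- unclass(drr)
  if (!is.null(roi)) {
    a <- crop_roi(a, roi); b <- crop_roi(b, roi)
    if (!is.null(mask)) mask <- crop_roi(mask, roi)
  }
  overlap <- as.vector(t(a == 1 & b == 1))
  if (!is.null(mask)) overlap <- overlap[!as.vector(t(mask))]
  n <- noa(res)
  denom <- n + sum(overlap)
  if (denom == 0) stop("relative NOA undefined: no lit pixels in either image")
  n / denom
}

# ---- internal registration machinery ---------------------------------------

# Residual-derivative sign: PD = DR - DRR implies dPD/dp = -dDRR/dp. The
# central-difference Jacobian uses this sign; flipping it would only negate
# the Jacobian globally and leave the damped least-squares step unchanged.
NOA_JACOBIAN_SIGN <- -1

.mesh_data <- function(mesh) {
  list(vertices = mesh$vertices, faces0 = t(mesh$faces) - 1L)
}

# Prepare one view for registration: fixed ROI from the DR segmentation,
# row-major DR residual vector, keep-vector from the drop-out mask.
.prepare_view <- function(dr, camera, mask = NULL, margin_px = 20L,
                          threshold = 0.5) {
  stopifnot(inherits(dr, "radiograph"), inherits(camera, "projection_model"))
  if (!isTRUE(all.equal(dr$pixel_spacing, camera$pixel_spacing)))
    stop("radiograph and camera pixel spacings differ")
  if (!identical(dim(dr$intensity),
                 c(camera$image_height, camera$image_width)))
    stop("radiograph dimensions do not match the camera raster")
  if (!is.null(mask) && !identical(dim(mask), dim(dr$intensity)))
    stop("mask dimensions do not match the radiograph")
  # grayscale DR is used as-is: enhancement (histogram equalization, gamma)
  # is a preprocessing step the caller applies before registration, so the
  # residual target here is already the enhanced image
  seg <- if (dr$is_binary) dr else threshold_segment(dr, threshold)
  drres <- dr$intensity
  roi <- compute_roi(seg, margin_px)
  keep <- NULL
  if (!is.null(mask)) {
    mroi <- crop_roi(mask, roi)
    if (any(mroi)) keep <- !as.vector(t(mroi))
  }
  drvec <- as.vector(t(crop_roi(drres, roi)))
  if (!is.null(keep)) drvec <- drvec[keep]
  list(camera = camera, roi = roi,
       window = c(roi$x0, roi$y0, roi$width, roi$height),
       drvec = drvec, keep = keep, binary = dr$is_binary)
}

# Rasterize the posed mesh over the view's ROI window, returned as a
# row-major (y outer, x inner) numeric vector. The x/y swap in the
# .rasterize_cpp call makes R's column-major vectorization come out
# row-major in image order.
.raster_vec <- function(ctx, md, params, center) {
  tf <- pose_to_transform(pose6(params[1], params[2], params[3],
                                params[4], params[5], params[6],
                                rotation_center = center))
  verts <- apply_transform(tf, md$vertices)
  depths <- projection_depths(ctx$camera, verts)
  if (any(depths <= 0))
    stop("unrenderable pose: mesh vertex at non-positive depth")
  m <- ctx$camera$matrix
  h <- verts %*% t(m[, 1:3, drop = FALSE])
  px <- (h[, 1] + m[1, 4]) / depths
  py <- (h[, 2] + m[2, 4]) / depths
  w <- ctx$window
  v <- .rasterize_vec_cpp(py, px, md$faces0,
                          w[2], w[1], w[4], w[3])
  if (!is.null(ctx$keep)) v[ctx$keep] else v
}

.view_residual <- function(ctx, md, params, center) {
  ctx$drvec - .raster_vec(ctx, md, params, center)
}

.residuals <- function(ctxs, md, params, center) {
  lapply(ctxs, .view_residual, md = md, params = params, center = center)
}

.ssr <- function(res) sum(vapply(res, function(r) sum(r * r), numeric(1)))

# One central-difference Jacobian per view: column d is
# sign * (DRR(p + eps e_d) - DRR(p - eps e_d)) / (2 eps), rows in residual
# order. Exactly two renders per DOF per view.
.view_jacobian <- function(ctx, md, params, center, eps) {
  cols <- vector("list", 6L)
  for (d in 1:6) {
    pp <- params; pp[d] <- pp[d] + eps
    pm <- params; pm[d] <- pm[d] - eps
    cols[[d]] <- NOA_JACOBIAN_SIGN *
      (.raster_vec(ctx, md, pp, center) - .raster_vec(ctx, md, pm, center)) /
      (2 * eps)
  }
  do.call(cbind, cols)
}

.jacobians <- function(ctxs, md, params, center, eps) {
  lapply(ctxs, .view_jacobian, md = md, params = params, center = center,
         eps = eps)
}

# One Levenberg-Marquardt stage at fixed difference spacing eps.
# Damping lambda*I, initialized to 1e-3 * trace(JtJ)/6, x10 when a trial
# step increases the residual, /10 after an acceptance. A trial step that
# leaves the residual exactly unchanged flipped no pixel (or slid along a
# plateau of the piecewise-constant objective): the step is lengthened
# (lambda/10) rather than damped. Terminates on zero residual, relative
# residual reduction < rel_tol, failure to find any improving step, or
# max_iter; a step-norm cutoff is deliberately not used, because on the
# staircase landscape small accepted steps routinely precede larger valley
# moves.
.stage_lm <- function(ctxs, md, pose, eps, max_iter = 100L, rel_tol = 1e-6) {
  params <- pose_params(pose)
  center <- pose$rotation_center
  res <- .residuals(ctxs, md, params, center)
  ssr <- .ssr(res)
  iters <- 0L
  lambda <- NULL
  term <- NA_character_
  if (ssr == 0) term <- "zero_residual"
  plateau <- 0L
  while (is.na(term)) {
    if (iters >= max_iter) { term <- "max_iter"; break }
    js <- .jacobians(ctxs, md, params, center, eps)
    iters <- iters + 1L
    a <- Reduce(`+`, lapply(js, crossprod))
    g <- drop(Reduce(`+`, Map(crossprod, js, res)))
    if (is.null(lambda)) {
      lambda <- 1e-3 * sum(diag(a)) / 6
      if (!is.finite(lambda) || lambda <= 0) lambda <- 1e-3
    }
    accepted <- FALSE
    for (k in 1:25) {
      step <- tryCatch(solve(a + diag(lambda, 6L), -g),
                       error = function(e) NULL)
      if (is.null(step)) { lambda <- lambda * 10; next }
      trial <- params + step
      tres <- tryCatch(.residuals(ctxs, md, trial, center),
                       error = function(e) NULL)
      if (is.null(tres)) { lambda <- lambda * 10; next }
      tssr <- .ssr(tres)
      if (tssr < ssr) {
        reduction <- ssr - tssr
        params <- trial; res <- tres
        old_ssr <- ssr; ssr <- tssr
        lambda <- lambda / 10
        accepted <- TRUE
        plateau <- 0L
        if (ssr == 0) term <- "zero_residual"
        else if (reduction < rel_tol * old_ssr) term <- "residual_reduction"
        break
      } else if (tssr > ssr) {
        lambda <- lambda * 10           # overshoot: damp harder
      } else if (sqrt(sum(step^2)) < 1e-12) {
        # flat with a vanishing step: lengthen it
        lambda <- lambda / 10
        if (lambda < 1e-14) break
      } else if (plateau < 5L) {
        # plateau walk: the acceptance rule tolerates equal residuals, and
        # on the staircase landscape walking a flat (bounded, so a drift
        # cannot cycle forever) often reaches a descending edge the damped
        # step could not see from the previous pose
        params <- trial; res <- tres
        accepted <- TRUE
        plateau <- plateau + 1L
        break
      } else {
        lambda <- lambda / 10
        if (lambda < 1e-14) break
      }
    }
    if (!accepted) term <- "no_improvement"
  }
  list(pose = pose_with_params(pose, params), iterations = iters,
       residual_ss = ssr, termination = term)
}

# ---- exported registration surface -----------------------------------------

.as_view_list <- function(views) {
  lapply(views, function(v) {
    stopifnot(is.list(v), !is.null(v$dr), !is.null(v$camera))
    list(dr = v$dr, camera = v$camera, mask = v$mask)
  })
}

#' Central-difference Jacobian of the pixel-difference residual
#'
#' One column per pose parameter in the order (rx, ry, rz, tx, ty, tz);
#' rotations are perturbed by `eps` degrees, translations by `eps` mm. Each
#' column requires exactly two silhouette renders per view. Rows follow the
#' stacked residual ordering: first view's unmasked ROI pixels (row-major)
#' first, then the second view's.
#'
#' @param mesh a [triangle_mesh()].
#' @param pose the [pose6()] at which to differentiate.
#' @param eps difference spacing, mm or degrees; > 0.
#' @param views list of views, each `list(dr =, camera =, mask = NULL)`.
#' @param margin_px ROI margin around the DR segmentation, px.
#' @param threshold segmentation threshold for grayscale DR.
#' @return numeric matrix with 6 columns.
#' @export
jacobian_central_diff <- function(mesh, pose, eps, views,
                                  margin_px = 20L, threshold = 0.5) {
  stopifnot(eps > 0)
  views <- .as_view_list(views)
  ctxs <- lapply(views, function(v)
    .prepare_view(v$dr, v$camera, v$mask, margin_px, threshold))
  md <- .mesh_data(mesh)
  do.call(rbind, .jacobians(ctxs, md, pose_params(pose),
                            pose$rotation_center, eps))
}

#' One Levenberg-Marquardt optimization stage
#'
#' Damped Gauss-Newton iterations on the stacked AP+LAT pixel-difference
#' residual at a fixed central-difference spacing `eps`. Steps are accepted
#' only if the residual sum of squares does not increase, so the returned
#' pose never fits worse than the starting pose.
#'
#' @inheritParams jacobian_central_diff
#' @param pose0 starting [pose6()].
#' @param max_iter iteration cap for the stage.
#' @return list with `pose`, `iterations`, `residual_ss`, `termination`.
#' @export
lm_stage <- function(mesh, views, pose0, eps, max_iter = 100L,
                     margin_px = 20L, threshold = 0.5) {
  stopifnot(eps > 0)
  views <- .as_view_list(views)
  ctxs <- lapply(views, function(v)
    .prepare_view(v$dr, v$camera, v$mask, margin_px, threshold))
  .stage_lm(ctxs, .mesh_data(mesh), pose0, eps, max_iter = max_iter)
}

#' Intensity-based nonoverlapping-area 2D-3D registration
#'
#' Recovers the 6-DOF pose of the mesh from a calibrated stereo pair of
#' radiographs by minimizing the nonoverlapping area between the real
#' segmentations and rendered binary silhouettes. The optimization runs one
#' Levenberg-Marquardt stage per difference spacing in `schedule`
#' (coarse-to-fine), warm-starting each stage from the previous one. The
#' region of interest is computed once per view from the DR segmentation
#' (enlarged by `margin_px`) and kept fixed, so the objective does not change
#' mid-optimization. Grayscale radiographs are used directly as real-valued
#' residual targets against the binary DRR; enhancement (histogram
#' equalization, [equalize_histogram()], or gamma adjustment) is a
#' preprocessing step applied before registration, so pass the enhanced
#' image in which the implant approaches the top of the intensity range.
#'
#' @param views list of exactly two views (anterior-posterior first, lateral
#'   second), each `list(dr = radiograph, camera = projection_model,
#'   mask = NULL)`; `mask` is an optional logical drop-out matrix.
#' @param mesh the implant [triangle_mesh()], mm.
#' @param pose0 initial [pose6()] estimate; its rotation center is used for
#'   the whole registration. The validated capture range is about
#'   ±5 mm / ±5 degrees per axis.
#' @param schedule strictly decreasing difference spacings, mm-or-degrees;
#'   default `c(10, 1, 0.1, 0.01, 0.001)`.
#' @param margin_px ROI margin, px; must exceed the largest expected
#'   initial-pose silhouette displacement.
#' @param threshold segmentation threshold for grayscale DR, fraction of range.
#' @param max_iter per-stage iteration cap.
#' @return object of class `noa_registration`: final pose, per-stage
#'   iteration counts, residual NOA (sum of squares), relative NOA (binary
#'   mode only, else `NA`), and a convergence flag.
#' @export
noa_register <- function(views, mesh, pose0,
                         schedule = c(10, 1, 0.1, 0.01, 0.001),
                         margin_px = 20L, threshold = 0.5,
                         max_iter = 100L) {
  stopifnot(length(views) == 2L, all(diff(schedule) < 0), all(schedule > 0))
  t0 <- proc.time()[["elapsed"]]
  views <- .as_view_list(views)
  ctxs <- lapply(views, function(v)
    .prepare_view(v$dr, v$camera, v$mask, margin_px, threshold))
  md <- .mesh_data(mesh)
  binary <- all(vapply(ctxs, `[[`, logical(1), "binary"))

  pose <- pose0
  stages <- vector("list", length(schedule))
  for (i in seq_along(schedule)) {
    st <- .stage_lm(ctxs, md, pose, schedule[i], max_iter = max_iter)
    pose <- st$pose
    stages[[i]] <- tibble::tibble(eps = schedule[i],
                                  iterations = st$iterations,
                                  residual_ss = st$residual_ss,
                                  termination = st$termination)
  }
  stages <- dplyr::bind_rows(stages)

  final_res <- .residuals(ctxs, md, pose_params(pose), pose$rotation_center)
  final_noa <- .ssr(final_res)
  rel <- NA_real_
  if (binary) {
    overlap <- 0
    for (i in seq_along(ctxs)) {
      drr <- .raster_vec(ctxs[[i]], md, pose_params(pose),
                         pose$rotation_center)
      overlap <- overlap + sum(ctxs[[i]]$drvec == 1 & drr == 1)
    }
    rel <- final_noa / (final_noa + overlap)
  }
  structure(
    list(pose = pose,
         stages = stages,
         total_iterations = sum(stages$iterations),
         noa = final_noa,
         relative_noa = rel,
         converged = !any(stages$termination == "max_iter"),
         mode = if (binary) "binary" else "grayscale",
         rois = lapply(ctxs, `[[`, "roi"),
         margin_px = as.integer(margin_px),
         threshold = threshold,
         wall_time = proc.time()[["elapsed"]] - t0),
    class = "noa_registration")
}

#' @export
print.noa_registration <- function(x, ...) {
  cat(sprintf("<noa_registration> %s mode, %s\n", x$mode,
              if (x$converged) "converged" else "iteration cap reached"))
  print(x$pose)
  cat(sprintf("  NOA %.6g%s, %d iterations over %d stages (%.2f s)\n",
              x$noa,
              if (!is.na(x$relative_noa))
                sprintf(" (relative %.4g%%)", 100 * x$relative_noa) else "",
              x$total_iterations, nrow(x$stages), x$wall_time))
  invisible(x)
}
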