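#' Render a binary silhouette DRR
#'
#' Rasterizes the posed mesh through the projection model: a pixel is 1 iff
#' its center lies inside the 2D projection of at least one triangle
#' (inclusive edge rule). The silhouette is the union of all projected
#' triangles, so no depth buffer is used and back faces are not culled.
#'
#' @param mesh a [triangle_mesh()].
#' @param camera a [projection_model()] with valid raster dimensions.
#' @param pose a [pose6()]; defaults to the identity pose.
#' @param window optional integer vector `c(x0, y0, width, height)` (0-based
#'   pixel units) restricting rasterization to a sub-window, e.g. a region of
#'   interest; default is the full raster.
#' @return an integer 0/1 matrix (`height` rows x `width` cols) of class
#'   `silhouette`, with attributes `pixel_spacing` and `window`.
#' @export
render_silhouette <- function(mesh, camera, pose = NULL, window = NULL) {
  verts <- mesh$vertices
  if (!is.null(pose)) verts <- apply_transform(pose_to_transform(pose), verts)
  depths <- projection_depths(camera, verts)
  if (any(depths <= 0))
    stop("unrenderable pose: mesh vertex at non-positive depth")
  h <- verts %*% t(camera$matrix[, 1:3, drop = FALSE])
  px <- (h[, 1:2, drop = FALSE] +
           matrix(camera$matrix[1:2, 4], nrow(h), 2L, byrow = TRUE)) / depths
  if (is.null(window))
    window <- c(0L, 0L, camera$image_width, camera$image_height)
  out <- .rasterize_cpp(px[, 1], px[, 2], t(mesh$faces) - 1L,
                        as.integer(window[1]), as.integer(window[2]),
                        as.integer(window[3]), as.integer(window[4]))
  structure(out, class = "silhouette",
            pixel_spacing = camera$pixel_spacing, window = as.integer(window))
}

#' @export
print.silhouette <- function(x, ...) {
  cat(sprintf("<silhouette> %d x %d px, %d lit (%.3g mm/px)\n",
              nrow(x), ncol(x), sum(x), attr(x, "pixel_spacing")))
  invisible(x)
}

#' Write a silhouette (or any binary raster) as an 8-bit PNG
#' @param sil 0/1 matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_silhouette_png <- function(sil, path) {
  png::writePNG(matrix(as.numeric(sil), nrow(sil)), path)
  invisible(path)
}
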