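SCHEMA_POSE <- "noarsa/pose/1"
SCHEMA_CALIBRATION <- "noarsa/calibration/1"
SCHEMA_RESULT <- "noarsa/result/1"

check_schema <- function(doc, expected, path) {
  if (is.null(doc$schema))
    stop("missing 'schema' field in ", path)
  if (!identical(doc$schema, expected))
    stop("unsupported schema version '", doc$schema, "' in ", path,
         " (expected '", expected, "')")
}

#' Write / read a pose as JSON
#'
#' Angles in degrees, translations and the rotation center in millimetres;
#' floats keep full precision, so a round trip is exact.
#'
#' @param pose a [pose6()].
#' @param path JSON file path.
#' @return `read_pose` returns a [pose6()]; `write_pose` returns `path`
#'   invisibly.
#' @export
write_pose <- function(pose, path) {
  p <- as.list(pose_params(pose))
  doc <- c(list(schema = SCHEMA_POSE), p,
           list(rotation_center = pose$rotation_center))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pose
#' @export
read_pose <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  check_schema(doc, SCHEMA_POSE, path)
  for (f in c("rx", "ry", "rz", "tx", "ty", "tz"))
    if (is.null(doc[[f]])) stop("pose file missing field '", f, "': ", path)
  pose6(doc$rx, doc$ry, doc$rz, doc$tx, doc$ty, doc$tz,
        rotation_center = if (is.null(doc$rotation_center)) c(0, 0, 0)
                          else as.numeric(doc$rotation_center))
}

#' Write / read a stereo calibration as JSON
#'
#' Per-view 3x4 projection matrix (row-major), raster dimensions and pixel
#' spacing.
#'
#' @param views named list of [projection_model()]s (conventionally `ap`,
#'   `lat`).
#' @param path JSON file path.
#' @return `read_calibration` returns the named list of models;
#'   `write_calibration` returns `path` invisibly.
#' @export
write_calibration <- function(views, path) {
  doc <- list(
    schema = SCHEMA_CALIBRATION,
    views = lapply(names(views), function(nm) {
      v <- views[[nm]]
      list(name = nm, matrix = as.vector(t(v$matrix)),
           image_width = v$image_width, image_height = v$image_height,
           pixel_spacing = v$pixel_spacing)
    }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  check_schema(doc, SCHEMA_CALIBRATION, path)
  vs <- doc$views
  if (is.data.frame(vs)) vs <- split(vs, seq_len(nrow(vs)))
  out <- list()
  for (v in vs) {
    v <- as.list(v)
    m <- unlist(v$matrix)
    if (length(m) != 12L)
      stop("calibration view '", v$name, "' has a malformed matrix: ", path)
    out[[as.character(v$name)]] <- projection_model(
      matrix(m, 3L, 4L, byrow = TRUE),
      v$image_width, v$image_height, v$pixel_spacing)
  }
  out
}

#' Write / read a marker set as CSV
#'
#' Columns `label, x, y, z` (mm) for 3D beads, `label, x, y` (px) for 2D
#' detections.
#'
#' @param markers a [marker_set()] or data frame.
#' @param path CSV path.
#' @return `read_markers` returns a tibble; a 3-coordinate file gains class
#'   `marker_set`. `write_markers` returns `path` invisibly.
#' @export
write_markers <- function(markers, path) {
  utils::write.csv(as.data.frame(markers), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_markers
#' @export
read_markers <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("label", "x", "y") %in% names(d)))
    stop("marker file must have columns label, x, y[, z]: ", path)
  if ("z" %in% names(d)) marker_set(as.matrix(d[, c("x", "y", "z")]), d$label)
  else tibble::as_tibble(d)
}

#' Write a registration result record as JSON
#'
#' A self-describing document: schema version, configuration echo, MD5
#' checksums of the input files, the final pose, per-stage iteration counts,
#' NOA statistics and wall time.
#'
#' @param result a `noa_registration`.
#' @param path output JSON path.
#' @param config named list echoed into the record.
#' @param inputs character vector of input file paths to checksum.
#' @return `path`, invisibly.
#' @export
write_result_record <- function(result, path, config = list(),
                                inputs = character()) {
  sums <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  doc <- list(
    schema = SCHEMA_RESULT,
    config = config,
    input_checksums = sums,
    pose = c(as.list(pose_params(result$pose)),
             list(rotation_center = result$pose$rotation_center)),
    stages = result$stages,
    total_iterations = result$total_iterations,
    noa = result$noa,
    relative_noa_pct = if (is.na(result$relative_noa)) NULL
                       else 100 * result$relative_noa,
    converged = result$converged,
    mode = result$mode,
    wall_time = result$wall_time)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a registration result record
#' @param path JSON path written by [write_result_record()].
#' @return the parsed record (list).
#' @export
read_result_record <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  check_schema(doc, SCHEMA_RESULT, path)
  doc
}
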