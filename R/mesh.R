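#' Triangle mesh constructor
#'
#' Implant surface geometry: vertex positions in millimetres plus triangle
#' connectivity. Duplicate vertices are tolerated — silhouette rendering is
#' insensitive to them.
#'
#' @param vertices n x 3 numeric matrix, mm.
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @return object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3L)
  stopifnot(ncol(vertices) == 3L, all(is.finite(vertices)), nrow(faces) >= 1L)
  if (min(faces) < 1L || max(faces) > nrow(vertices))
    stop("face indices out of range")
  structure(list(vertices = vertices, faces = faces), class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("<triangle_mesh> %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Mesh centroid (mean vertex position, mm)
#' @param mesh a [triangle_mesh()].
#' @return length-3 numeric vector.
#' @export
mesh_centroid <- function(mesh) colMeans(mesh$vertices)

#' Apply a rigid transform to a mesh
#' @param mesh a [triangle_mesh()].
#' @param tf a [rigid_transform()].
#' @return the transformed [triangle_mesh()].
#' @export
transform_mesh <- function(mesh, tf) {
  triangle_mesh(apply_transform(tf, mesh$vertices), mesh$faces)
}

#' Check that every mesh edge is shared by exactly two faces
#' @param mesh a [triangle_mesh()].
#' @return logical scalar.
#' @export
is_watertight <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

#' Read a triangle mesh from STL, PLY or OBJ
#'
#' Format is chosen by file extension. STL may be binary or ASCII (detected
#' from content); PLY must be ASCII; OBJ supports `v`/`f` records with
#' triangular (or fan-triangulated polygonal) faces. Coordinates are taken
#' as millimetres.
#'
#' @param path file path.
#' @return a [triangle_mesh()].
#' @export
load_mesh <- function(path) {
  if (!file.exists(path)) stop("mesh file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  mesh <- switch(ext,
    stl = read_stl(path),
    ply = read_ply(path),
    obj = read_obj(path),
    stop("unsupported mesh format: .", ext))
  if (nrow(mesh$vertices) == 0L || nrow(mesh$faces) == 0L)
    stop("empty mesh: ", path)
  mesh
}

stl_is_ascii <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  head <- readBin(con, "raw", 512L)
  # keep printable ASCII and whitespace only: binary STL headers carry
  # arbitrary bytes that are not valid in any character encoding
  ok <- (head >= as.raw(32) & head <= as.raw(126)) |
    head %in% as.raw(c(9L, 10L, 13L))
  txt <- rawToChar(head[ok])
  grepl("^\\s*solid", txt, useBytes = TRUE) &&
    grepl("facet", txt, useBytes = TRUE)
}

read_stl <- function(path) {
  if (stl_is_ascii(path)) read_stl_ascii(path) else read_stl_binary(path)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) == 0L || length(vl) %% 3L != 0L)
    stop("malformed ASCII STL: ", path)
  nums <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(x)
    as.numeric(x[2:4])))
  n <- nrow(nums)
  triangle_mesh(nums, matrix(seq_len(n), ncol = 3L, byrow = TRUE))
}

read_stl_binary <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  readBin(con, "raw", 80L)
  nt <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (!length(nt) || nt < 1L) stop("malformed binary STL: ", path)
  rec <- readBin(con, "raw", nt * 50L)
  if (length(rec) < nt * 50L) stop("truncated binary STL: ", path)
  idx <- rep(seq(0L, (nt - 1L) * 50L, by = 50L), each = 36L) +
    rep(12L + seq_len(36L), times = nt)
  vals <- readBin(rec[idx], "numeric", n = nt * 9L, size = 4L,
                  endian = "little")
  verts <- matrix(vals, ncol = 3L, byrow = TRUE)
  triangle_mesh(verts, matrix(seq_len(3L * nt), ncol = 3L, byrow = TRUE))
}

#' Write a triangle mesh as STL
#' @param mesh a [triangle_mesh()].
#' @param path output path.
#' @param ascii write ASCII STL (default binary).
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, ascii = FALSE) {
  v <- mesh$vertices; f <- mesh$faces
  if (ascii) {
    con <- file(path, "w"); on.exit(close(con))
    writeLines("solid mesh", con)
    for (i in seq_len(nrow(f))) {
      writeLines(c("  facet normal 0 0 0", "    outer loop"), con)
      for (j in 1:3)
        writeLines(sprintf("      vertex %.9g %.9g %.9g",
                           v[f[i, j], 1], v[f[i, j], 2], v[f[i, j], 3]), con)
      writeLines(c("    endloop", "  endfacet"), con)
    }
    writeLines("endsolid mesh", con)
  } else {
    con <- file(path, "wb"); on.exit(close(con))
    writeBin(raw(80L), con)
    writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
    for (i in seq_len(nrow(f))) {
      writeBin(numeric(3L), con, size = 4L, endian = "little")
      writeBin(as.numeric(t(v[f[i, ], ])), con, size = 4L, endian = "little")
      writeBin(as.raw(c(0L, 0L)), con)
    }
  }
  invisible(path)
}

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!grepl("^ply", lines[1])) stop("not a PLY file: ", path)
  if (!any(grepl("format ascii", lines))) stop("only ASCII PLY supported")
  endh <- match("end_header", trimws(lines))
  nv <- as.integer(sub(".*element vertex\\s+", "",
                       grep("element vertex", lines, value = TRUE)[1]))
  nf <- as.integer(sub(".*element face\\s+", "",
                       grep("element face", lines, value = TRUE)[1]))
  if (is.na(nv) || is.na(nf)) stop("malformed PLY header: ", path)
  body <- lines[(endh + 1L):length(lines)]
  vparts <- strsplit(trimws(body[seq_len(nv)]), "\\s+")
  verts <- do.call(rbind, lapply(vparts, function(x) as.numeric(x[1:3])))
  fparts <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
  faces <- do.call(rbind, lapply(fparts, function(x) {
    k <- as.integer(x[1])
    if (k != 3L) stop("only triangular PLY faces supported")
    as.integer(x[2:4]) + 1L
  }))
  triangle_mesh(verts, faces)
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", lines, value = TRUE)
  fl <- grep("^f\\s", lines, value = TRUE)
  verts <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(x)
    as.numeric(x[2:4])))
  faces <- do.call(rbind, lapply(strsplit(trimws(fl), "\\s+"), function(x) {
    idx <- as.integer(sub("/.*", "", x[-1]))
    if (length(idx) < 3L) stop("OBJ face with fewer than 3 vertices")
    # fan-triangulate polygons
    cbind(idx[1], idx[2:(length(idx) - 1L)], idx[3:length(idx)])
  }))
  triangle_mesh(verts, faces)
}
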