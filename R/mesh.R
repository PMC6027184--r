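# Triangle surface meshes. Vertices are an n x 3 matrix in millimetres,
# faces an m x 3 integer matrix of 1-based vertex indices.

#' Construct a triangle surface mesh
#'
#' @param vertices n x 3 numeric matrix of vertex positions (mm).
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @param body_name label of the body the surface belongs to.
#' @return a `surface_mesh` object.
#' @export
surface_mesh <- function(vertices, faces, body_name = "") {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3L)
  if (ncol(vertices) != 3L) stop("vertices must be n x 3")
  if (nrow(faces) == 0L) stop("empty mesh: zero faces")
  if (any(faces < 1L) || any(faces > nrow(vertices)))
    stop("face indices out of range")
  m <- structure(list(vertices = vertices, faces = faces,
                      body_name = body_name),
                 class = "surface_mesh")
  a <- triangle_areas(m)
  if (any(a <= 0)) stop("mesh contains degenerate (zero-area) triangles")
  m
}

#' @export
print.surface_mesh <- function(x, ...) {
  bb <- apply(x$vertices, 2L, range)
  cat(sprintf("surface_mesh '%s': %d vertices, %d faces, area %.2f mm^2\n",
              x$body_name, nrow(x$vertices), nrow(x$faces), mesh_area(x)))
  cat(sprintf("  bbox: [%.2f, %.2f] x [%.2f, %.2f] x [%.2f, %.2f] mm\n",
              bb[1L, 1L], bb[2L, 1L], bb[1L, 2L], bb[2L, 2L], bb[1L, 3L], bb[2L, 3L]))
  invisible(x)
}

# per-face edge vectors and cross products, shared by areas/normals
.face_cross <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  e2 <- v[f[, 3L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
        e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
        e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
}

triangle_areas <- function(mesh) {
  cr <- .face_cross(mesh)
  0.5 * sqrt(rowSums(cr * cr))
}

triangle_normals <- function(mesh) {
  cr <- .face_cross(mesh)
  cr / sqrt(rowSums(cr * cr))
}

triangle_centroids <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  (v[f[, 1L], , drop = FALSE] + v[f[, 2L], , drop = FALSE] +
     v[f[, 3L], , drop = FALSE]) / 3
}

#' Total surface area of a mesh
#' @param mesh a `surface_mesh`.
#' @return area in mm^2.
#' @export
mesh_area <- function(mesh) sum(triangle_areas(mesh))

#' Load a triangle mesh from STL (ASCII or binary) or OBJ
#'
#' The artifact works in millimetres throughout; `units` rescales inputs
#' authored in other units.
#'
#' @param path file path; format is inferred from the extension (`.stl`,
#'   `.obj`) and, for STL, from the file header.
#' @param units one of `"mm"`, `"m"`, `"cm"`: unit the file was authored in.
#' @param body_name label for the mesh; defaults to the file stem.
#' @param quiet suppress the size/bounding-box message.
#' @return a `surface_mesh` in millimetres.
#' @export
load_mesh <- function(path, units = c("mm", "m", "cm"), body_name = NULL,
                      quiet = TRUE) {
  units <- match.arg(units)
  if (!file.exists(path)) stop("mesh file does not exist: ", path)
  if (is.null(body_name))
    body_name <- sub("\\.[^.]*$", "", basename(path))
  ext <- tolower(sub(".*\\.", "", path))
  mesh <- switch(ext,
                 stl = read_stl(path, body_name),
                 obj = read_obj(path, body_name),
                 stop("unsupported mesh format: .", ext, " (expected STL or OBJ)"))
  scale <- c(mm = 1, m = 1000, cm = 10)[[units]]
  if (scale != 1) mesh$vertices <- mesh$vertices * scale
  if (!quiet) {
    bb <- apply(mesh$vertices, 2L, range)
    message(sprintf("loaded '%s': %d vertices, %d faces, bbox diagonal %.3f mm",
                    path, nrow(mesh$vertices), nrow(mesh$faces),
                    sqrt(sum((bb[2L, ] - bb[1L, ])^2))))
  }
  mesh
}

read_stl <- function(path, body_name) {
  con <- file(path, "rb")
  head <- readBin(con, "raw", 80L)
  close(con)
  txt <- rawToChar(head[head != as.raw(0L)])
  # ASCII STL starts with "solid" AND contains "facet" somewhere early;
  # binary files sometimes also start with "solid", so check facet too.
  is_ascii <- grepl("^\\s*solid", txt)
  if (is_ascii) {
    first <- tryCatch(readLines(path, n = 40L, warn = FALSE), error = function(e) "")
    is_ascii <- any(grepl("facet", first))
  }
  if (is_ascii) read_stl_ascii(path, body_name) else read_stl_binary(path, body_name)
}

read_stl_ascii <- function(path, body_name) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) == 0L || length(vl) %% 3L != 0L)
    stop("malformed ASCII STL (vertex count not a multiple of 3): ", path)
  nums <- suppressWarnings(
    matrix(as.numeric(unlist(strsplit(trimws(vl), "\\s+"))[c(FALSE, TRUE, TRUE, TRUE)]),
           ncol = 3L, byrow = TRUE))
  if (anyNA(nums)) stop("malformed ASCII STL (non-numeric vertex): ", path)
  build_indexed_mesh(nums, body_name)
}

read_stl_binary <- function(path, body_name) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80L)
  ntri <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (is.na(ntri) || ntri <= 0L || sz < 84 + 50 * ntri)
    stop("malformed binary STL (truncated or empty): ", path)
  raw <- readBin(con, "raw", 50L * ntri)
  # each record: 12 floats (48 bytes) + 2-byte attribute
  idx <- rep(seq(0L, ntri - 1L) * 50L, each = 48L) + seq_len(48L)
  fl <- readBin(raw[idx], "numeric", n = 12L * ntri, size = 4L, endian = "little")
  m <- matrix(fl, ncol = 12L, byrow = TRUE)
  verts <- matrix(t(m[, 4:12, drop = FALSE]), ncol = 3L, byrow = TRUE)
  build_indexed_mesh(verts, body_name)
}

read_obj <- function(path, body_name) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", lines, value = TRUE)
  fl <- grep("^f\\s", lines, value = TRUE)
  if (length(fl) == 0L) stop("empty mesh (no faces) in OBJ: ", path)
  verts <- matrix(as.numeric(unlist(lapply(strsplit(trimws(vl), "\\s+"),
                                           function(x) x[2:4]))),
                  ncol = 3L, byrow = TRUE)
  faces <- t(vapply(strsplit(trimws(fl), "\\s+"), function(x) {
    ix <- as.integer(sub("/.*", "", x[-1L]))
    if (length(ix) != 3L) stop("only triangular OBJ faces are supported")
    ix
  }, integer(3L)))
  if (anyNA(verts) || anyNA(faces)) stop("malformed OBJ file: ", path)
  surface_mesh(verts, faces, body_name)
}

# de-duplicate soup vertices (exact match on rounded coordinates)
build_indexed_mesh <- function(verts, body_name) {
  key <- apply(round(verts, 9L), 1L, paste, collapse = ",")
  uid <- !duplicated(key)
  map <- match(key, key[uid])
  surface_mesh(verts[uid, , drop = FALSE],
               matrix(map, ncol = 3L, byrow = TRUE), body_name)
}

#' Write a mesh as ASCII STL
#' @param mesh a `surface_mesh`.
#' @param path output file path.
#' @export
write_stl <- function(mesh, path) {
  n <- triangle_normals(mesh)
  v <- mesh$vertices; f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  name <- if (nzchar(mesh$body_name)) mesh$body_name else "mesh"
  writeLines(paste("solid", name), con)
  fmt <- function(x) sprintf("%.9g %.9g %.9g", x[1L], x[2L], x[3L])
  out <- character(7L * nrow(f))
  k <- 0L
  for (i in seq_len(nrow(f))) {
    out[k + 1L] <- paste("  facet normal", fmt(n[i, ]))
    out[k + 2L] <- "    outer loop"
    out[k + 3L] <- paste("      vertex", fmt(v[f[i, 1L], ]))
    out[k + 4L] <- paste("      vertex", fmt(v[f[i, 2L], ]))
    out[k + 5L] <- paste("      vertex", fmt(v[f[i, 3L], ]))
    out[k + 6L] <- "    endloop"
    out[k + 7L] <- "  endfacet"
    k <- k + 7L
  }
  writeLines(out, con)
  writeLines(paste("endsolid", name), con)
  invisible(path)
}

# parametric grid -> triangle mesh helper used by the synthetic subject.
# fx(u, v) must return a length-3 point; u, v are numeric grids.
mesh_from_param <- function(fx, u, v, body_name = "", close_u = FALSE) {
  nu <- length(u); nv <- length(v)
  verts <- matrix(0, nu * nv, 3L)
  for (i in seq_len(nu)) for (j in seq_len(nv))
    verts[(i - 1L) * nv + j, ] <- fx(u[i], v[j])
  id <- function(i, j) (i - 1L) * nv + j
  faces <- list()
  iu_max <- if (close_u) nu else nu - 1L
  for (i in seq_len(iu_max)) {
    i2 <- if (i == nu) 1L else i + 1L
    for (j in seq_len(nv - 1L)) {
      faces[[length(faces) + 1L]] <- c(id(i, j), id(i2, j), id(i2, j + 1L))
      faces[[length(faces) + 1L]] <- c(id(i, j), id(i2, j + 1L), id(i, j + 1L))
    }
  }
  build_indexed_mesh_from_faces(verts, do.call(rbind, faces), body_name)
}

build_indexed_mesh_from_faces <- function(verts, faces, body_name) {
  key <- apply(round(verts, 9L), 1L, paste, collapse = ",")
  uid <- !duplicated(key)
  map <- match(key, key[uid])
  f2 <- matrix(map[faces], ncol = 3L)
  # drop degenerate faces produced by grid seams (duplicated vertices)
  keep <- f2[, 1L] != f2[, 2L] & f2[, 2L] != f2[, 3L] & f2[, 1L] != f2[, 3L]
  surface_mesh(verts[uid, , drop = FALSE], f2[keep, , drop = FALSE], body_name)
}
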