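#' Triangulated articulating surface
#'
#' Constructs a `surface_mesh`, the container used for every articulating
#' surface in the package: implant insert and femoral component, pin face,
#' plate and calibration ball. Vertex normals are area-weighted averages of
#' incident face normals; the per-vertex area is the barycentric one-third
#' split of incident face areas, so that the vertex areas partition the total
#' mesh area exactly.
#'
#' Coordinate frame (left-knee convention, right-handed): x = anterior (+),
#' y = superior (+), z = medial (+). Lengths are millimetres throughout.
#'
#' @param vertices numeric matrix, n x 3, vertex coordinates in mm.
#' @param faces integer matrix, m x 3, 1-based vertex indices per triangle.
#' @param grid optional structured-grid descriptor for heightfield meshes
#'   (see [make_primitive()]); a list with elements `index` (vertex-id matrix,
#'   rows = first grid axis, columns = z-columns). Required by the contact
#'   solver for the rigid counterface.
#' @param extra optional named list of generator metadata (e.g. `cor`, the
#'   centre of rotation recorded by [make_femoral_surface()]).
#'
#' @return An object of class `surface_mesh`: a list with `vertices`, `faces`,
#'   `vertex_normal` (unit rows), `vertex_area` (mm^2), `grid`, plus any
#'   `extra` entries.
#' @export
surface_mesh <- function(vertices, faces, grid = NULL, extra = list()) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix")
  n <- nrow(vertices)
  if (n < 3L || nrow(faces) < 1L) stop("mesh needs at least 3 vertices and 1 face")
  if (any(faces < 1L) || any(faces > n)) stop("face indices out of range")

  v1 <- vertices[faces[, 1L], , drop = FALSE]
  v2 <- vertices[faces[, 2L], , drop = FALSE]
  v3 <- vertices[faces[, 3L], , drop = FALSE]
  e1 <- v2 - v1
  e2 <- v3 - v1
  cr <- cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
              e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
              e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
  face_area2 <- sqrt(rowSums(cr^2))      # twice the face area
  face_area <- face_area2 / 2

  # vertex area: one third of incident face areas (exact partition)
  va <- numeric(n)
  third <- rep(face_area / 3, 3L)
  idx <- as.vector(faces)
  va_acc <- rowsum(third, idx)
  va[as.integer(rownames(va_acc))] <- va_acc[, 1L]

  # vertex normal: area-weighted face normals (cr is already area-weighted)
  vn <- matrix(0, n, 3L)
  for (k in 1:3) {
    acc <- rowsum(rep(cr[, k], 3L), idx)
    vn[as.integer(rownames(acc)), k] <- acc[, 1L]
  }
  nrm <- sqrt(rowSums(vn^2))
  nrm[nrm == 0] <- 1
  vn <- vn / nrm
  # orient normals with a positive superior (+y) component where defined:
  # every surface in this package is articulating "upwards"
  flip <- vn[, 2L] < 0
  vn[flip, ] <- -vn[flip, ]

  out <- c(list(vertices = vertices, faces = faces,
                vertex_normal = vn, vertex_area = va,
                face_area = face_area, grid = grid),
           extra)
  class(out) <- "surface_mesh"
  out
}

#' Total mesh surface area
#' @param mesh a [surface_mesh()].
#' @return total area in mm^2.
#' @export
mesh_area <- function(mesh) sum(mesh$face_area)

#' @export
print.surface_mesh <- function(x, ...) {
  bb <- apply(x$vertices, 2L, range)
  cat("surface_mesh:", nrow(x$vertices), "vertices,", nrow(x$faces), "faces\n")
  cat(sprintf("  area %.4g mm^2, bbox x[%.2f, %.2f] y[%.2f, %.2f] z[%.2f, %.2f] mm\n",
              mesh_area(x), bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  if (!is.null(x$grid)) cat("  structured grid:", paste(dim(x$grid$index), collapse = " x "), "\n")
  invisible(x)
}

#' Mesh summary as a list (JSON-ready)
#'
#' @param mesh a [surface_mesh()].
#' @param path optional path; when given the summary is written as JSON.
#' @return invisibly, a list with vertex/face counts, total area and
#'   bounding box.
#' @export
mesh_summary <- function(mesh, path = NULL) {
  bb <- apply(mesh$vertices, 2L, range)
  s <- list(n_vertices = nrow(mesh$vertices),
            n_faces = nrow(mesh$faces),
            area_mm2 = mesh_area(mesh),
            bbox = list(x = bb[, 1L], y = bb[, 2L], z = bb[, 3L]))
  if (!is.null(path)) {
    jsonlite::write_json(s, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(s)
}

#' Rigidly rotate a mesh
#'
#' Applies a 3 x 3 rotation matrix to vertices and normals. The structured
#' grid descriptor is preserved (grid topology is unchanged by a rigid map),
#' as is any recorded centre of rotation.
#'
#' @param mesh a [surface_mesh()].
#' @param rot 3 x 3 rotation matrix.
#' @return the rotated `surface_mesh`.
#' @export
rotate_mesh <- function(mesh, rot) {
  rot <- as.matrix(rot)
  stopifnot(all(dim(rot) == c(3L, 3L)))
  extra <- list()
  if (!is.null(mesh$cor)) extra$cor <- as.vector(mesh$cor %*% t(rot))
  if (!is.null(mesh$params)) extra$params <- mesh$params
  surface_mesh(mesh$vertices %*% t(rot), mesh$faces, grid = mesh$grid, extra = extra)
}

# ---- STL input/output -------------------------------------------------------

#' Read a surface mesh from an STL file
#'
#' Both the binary and the ASCII STL dialect are supported; the dialect is
#' auto-detected. Duplicate vertices shared between triangles are merged.
#' STL stores a bare triangle soup, so the structured-grid descriptor used by
#' the contact solver is not recoverable from file; meshes intended as the
#' rigid counterface should be regenerated parametrically.
#'
#' @param path file path.
#' @return a [surface_mesh()].
#' @export
read_stl <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sz <- file.info(path)$size
  if (is.na(sz) || sz == 0) stop("empty STL file: ", path)
  con <- file(path, "rb")
  head <- readBin(con, "raw", n = min(sz, 512))
  close(con)
  # dialect sniffing on raw bytes (binary headers need not be valid text):
  # ASCII files start with "solid" and contain "facet" early on
  starts_solid <- length(head) >= 5 && identical(head[1:5], charToRaw("solid"))
  has_facet <- length(head) >= 5 &&
    any(vapply(seq_len(max(length(head) - 4, 0)), function(i) {
      identical(head[i:(i + 4)], charToRaw("facet"))
    }, logical(1)))
  is_ascii <- starts_solid && has_facet
  if (!is_ascii && sz >= 84) {
    tri <- read_stl_binary(path, sz)
  } else if (is_ascii) {
    tri <- read_stl_ascii(path)
  } else {
    stop("not a recognisable STL file (neither binary nor ASCII dialect): ", path)
  }
  soup_to_mesh(tri)
}

read_stl_binary <- function(path, sz) {
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", n = 80L))
  ntri <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  if (ntri <= 0 || 84 + 50 * as.numeric(ntri) > sz + 1) {
    stop("corrupt binary STL (triangle count ", ntri, " inconsistent with file size)")
  }
  raw <- readBin(con, "raw", n = 50L * ntri)
  m <- matrix(raw, nrow = 50L)
  coords <- matrix(0, ntri, 9L)
  for (j in 1:9) {
    b <- as.vector(m[(12 + 4 * (j - 1) + 1):(12 + 4 * j), , drop = FALSE])
    coords[, j] <- readBin(b, "double", size = 4L, n = ntri, endian = "little")
  }
  coords
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vx <- grep("^\\s*vertex", lines, value = TRUE)
  if (length(vx) == 0 || length(vx) %% 3 != 0) {
    stop("corrupt ASCII STL: vertex count ", length(vx), " is not a multiple of 3")
  }
  nums <- t(vapply(strsplit(trimws(vx), "\\s+"),
                   function(s) as.numeric(s[2:4]), numeric(3)))
  ntri <- nrow(nums) / 3
  matrix(t(nums), nrow = ntri, byrow = TRUE)
}

# triangle soup (m x 9: v1 v2 v3 coords) -> merged surface_mesh
soup_to_mesh <- function(tri) {
  pts <- rbind(tri[, 1:3, drop = FALSE], tri[, 4:6, drop = FALSE], tri[, 7:9, drop = FALSE])
  ntri <- nrow(tri)
  ord <- c(matrix(seq_len(3 * ntri), nrow = ntri)[, c(1, 2, 3)])
  key <- paste(format(pts[, 1], digits = 10), format(pts[, 2], digits = 10),
               format(pts[, 3], digits = 10))
  uid <- match(key, unique(key))
  verts <- pts[!duplicated(uid), , drop = FALSE]
  faces <- matrix(uid, ncol = 3L)
  surface_mesh(verts, faces)
}

#' Write a surface mesh to an STL file
#'
#' @param mesh a [surface_mesh()].
#' @param path output path.
#' @param ascii write the ASCII dialect instead of binary (default binary).
#' @return invisibly, `path`.
#' @export
write_stl <- function(mesh, path, ascii = FALSE) {
  v <- mesh$vertices
  f <- mesh$faces
  p1 <- v[f[, 1L], , drop = FALSE]
  p2 <- v[f[, 2L], , drop = FALSE]
  p3 <- v[f[, 3L], , drop = FALSE]
  e1 <- p2 - p1; e2 <- p3 - p1
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2)); len[len == 0] <- 1
  n <- n / len
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid tkrwear", con)
    for (i in seq_len(nrow(f))) {
      writeLines(c(
        sprintf("  facet normal %.9e %.9e %.9e", n[i, 1], n[i, 2], n[i, 3]),
        "    outer loop",
        sprintf("      vertex %.9e %.9e %.9e", p1[i, 1], p1[i, 2], p1[i, 3]),
        sprintf("      vertex %.9e %.9e %.9e", p2[i, 1], p2[i, 2], p2[i, 3]),
        sprintf("      vertex %.9e %.9e %.9e", p3[i, 1], p3[i, 2], p3[i, 3]),
        "    endloop",
        "  endfacet"), con)
    }
    writeLines("endsolid tkrwear", con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(c(charToRaw("tkrwear binary STL"), raw(80 - 18)), con)
    writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
    block <- cbind(n, p1, p2, p3)
    for (i in seq_len(nrow(f))) {
      writeBin(as.numeric(block[i, ]), con, size = 4L, endian = "little")
      writeBin(raw(2), con)
    }
  }
  invisible(path)
}
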