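#' Triangle mesh of leaf surfaces
#'
#' Container for a triangulated plant (or plate) surface: a vertex matrix, a
#' face index matrix, and derived per-face geometry.  All downstream stages
#' (distortion, ray tracing, carbon scaling) consume this class.
#'
#' Face normals are canonicalised to have non-negative z; leaves are treated
#' as two-sided light interceptors, so the choice of side carries no
#' radiative meaning.
#'
#' @param vertices numeric matrix, n x 3, vertex coordinates in metres
#'   (z up, ground at z = 0).
#' @param faces integer matrix, m x 3, 1-based vertex indices.
#' @param leaf_id optional integer vector of length m labelling the leaf
#'   blade each face belongs to.  If `NULL`, faces are labelled by
#'   connected components over shared vertices.
#'
#' @return An object of class `triangle_mesh` with elements `vertices`,
#'   `faces`, `leaf_id`, and per-face `area` (m^2), `center` (m x 3) and
#'   `normal` (unit vectors, m x 3).
#' @export
triangle_mesh <- function(vertices, faces, leaf_id = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix")
  if (!all(is.finite(vertices))) stop("non-finite vertex coordinates")
  if (nrow(faces) > 0L &&
      (min(faces) < 1L || max(faces) > nrow(vertices))) {
    stop("face indices out of range")
  }
  geom <- face_geometry_raw(vertices, faces)
  bad <- which(geom$area <= 0 | !is.finite(geom$area))
  if (length(bad) > 0L) {
    stop("degenerate (zero-area) face at index ", bad[1L])
  }
  if (is.null(leaf_id)) {
    leaf_id <- label_leaves(vertices, faces)
  } else {
    leaf_id <- as.integer(leaf_id)
    if (length(leaf_id) != nrow(faces)) stop("leaf_id length must equal face count")
  }
  structure(
    list(vertices = vertices, faces = faces, leaf_id = leaf_id,
         area = geom$area, center = geom$center, normal = geom$normal),
    class = "triangle_mesh"
  )
}

# Cross-product geometry; internal, no validation.
face_geometry_raw <- function(vertices, faces) {
  a <- vertices[faces[, 1L], , drop = FALSE]
  b <- vertices[faces[, 2L], , drop = FALSE]
  c <- vertices[faces[, 3L], , drop = FALSE]
  e1 <- b - a
  e2 <- c - a
  cr <- cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
              e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
              e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
  nrm <- sqrt(rowSums(cr^2))
  normal <- cr / nrm
  # canonical orientation: non-negative z component
  flip <- !is.na(normal[, 3L]) & normal[, 3L] < 0
  normal[flip, ] <- -normal[flip, , drop = FALSE]
  list(area = nrm / 2, center = (a + b + c) / 3, normal = normal)
}

#' Per-face areas, centers and normals
#'
#' @param mesh a [triangle_mesh].
#' @return A list with `areas` (m^2), `centers` (m x 3 matrix) and `normals`
#'   (unit vectors with non-negative z).
#' @export
face_geometry <- function(mesh) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  list(areas = mesh$area, centers = mesh$center, normals = mesh$normal)
}

# Label faces by connected component over shared vertices: faces of one leaf
# blade (a connected strip) share a label.
label_leaves <- function(vertices, faces) {
  if (nrow(faces) == 0L) return(integer(0))
  edges <- rbind(faces[, c(1L, 2L)], faces[, c(2L, 3L)], faces[, c(1L, 3L)])
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nrow(vertices) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  as.integer(comp[faces[, 1L]])
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf(
    "<triangle_mesh> %d vertices, %d faces, %d leaves\n  area %.5f m^2, height %.4f m\n",
    nrow(x$vertices), nrow(x$faces), length(unique(x$leaf_id)),
    sum(x$area), max(x$vertices[, 3L])))
  invisible(x)
}

#' Leaf inclination relative to vertical
#'
#' Converts face normals to the field's leaf-angle convention: 0 degrees is
#' an upright (vertical) leaf section, 90 degrees a horizontal one.  With
#' two-sided leaves the sign of the normal is immaterial, so the angle is
#' computed from |n . z|.
#'
#' @param normal a unit 3-vector or an m x 3 matrix of unit normals.
#' @return Angle(s) from vertical in degrees, in \[0, 90\].
#' @export
leaf_angle_from_vertical <- function(normal) {
  if (is.null(dim(normal))) normal <- matrix(normal, nrow = 1L)
  nrm <- sqrt(rowSums(normal^2))
  if (any(abs(nrm - 1) > 1e-6)) stop("normals must be unit vectors")
  ang <- 90 - acos(pmin(1, abs(normal[, 3L]))) * 180 / pi
  pmin(90, pmax(0, ang))
}

#' Read a triangulated mesh from OBJ or ASCII PLY
#'
#' Quad (or larger) polygons are fan-triangulated; OBJ indices are 1-based
#' on file (kept 1-based internally), PLY indices 0-based on file.
#'
#' @param path file path.
#' @param format `"obj"`, `"ply"`, or `NULL` to infer from the extension.
#' @return A [triangle_mesh].
#' @export
read_mesh <- function(path, format = NULL) {
  if (!file.exists(path)) stop("cannot read mesh file: ", path)
  if (is.null(format)) {
    format <- tolower(tools::file_ext(path))
  }
  format <- match.arg(tolower(format), c("obj", "ply"))
  lines <- readLines(path, warn = FALSE)
  if (format == "obj") parse_obj(lines) else parse_ply(lines)
}

parse_obj <- function(lines) {
  toks <- strsplit(trimws(lines), "\\s+")
  verts <- list()
  faces <- list()
  for (tk in toks) {
    if (length(tk) == 0L) next
    if (tk[1L] == "v") {
      verts[[length(verts) + 1L]] <- as.numeric(tk[2:4])
    } else if (tk[1L] == "f") {
      idx <- as.integer(vapply(strsplit(tk[-1L], "/"), `[`, "", 1L))
      if (length(idx) < 3L) stop("face with fewer than 3 vertices")
      for (k in seq_len(length(idx) - 2L)) {
        faces[[length(faces) + 1L]] <- c(idx[1L], idx[k + 1L], idx[k + 2L])
      }
    }
  }
  if (length(verts) == 0L) stop("no vertices found in OBJ file")
  triangle_mesh(do.call(rbind, verts), do.call(rbind, faces))
}

parse_ply <- function(lines) {
  end <- match("end_header", trimws(lines))
  if (is.na(end)) stop("not an ASCII PLY file (no end_header)")
  header <- trimws(lines[seq_len(end)])
  if (!any(grepl("^format\\s+ascii", header))) {
    stop("only ASCII PLY is supported")
  }
  nv <- as.integer(sub("^element\\s+vertex\\s+", "",
                       grep("^element\\s+vertex", header, value = TRUE)[1L]))
  nf <- as.integer(sub("^element\\s+face\\s+", "",
                       grep("^element\\s+face", header, value = TRUE)[1L]))
  if (is.na(nv) || is.na(nf)) stop("PLY header lacks vertex/face elements")
  body <- trimws(lines[(end + 1L):length(lines)])
  body <- body[nzchar(body)]
  vl <- strsplit(body[seq_len(nv)], "\\s+")
  verts <- do.call(rbind, lapply(vl, function(x) as.numeric(x[1:3])))
  faces <- list()
  for (ln in body[nv + seq_len(nf)]) {
    x <- as.integer(strsplit(ln, "\\s+")[[1L]])
    k <- x[1L]
    idx <- x[1L + seq_len(k)] + 1L  # 0-based on file
    for (j in seq_len(k - 2L)) {
      faces[[length(faces) + 1L]] <- c(idx[1L], idx[j + 1L], idx[j + 2L])
    }
  }
  triangle_mesh(verts, do.call(rbind, faces))
}

#' Write a mesh as OBJ or ASCII PLY
#'
#' Coordinates are written with 17 significant digits so that a write/read
#' round trip preserves geometry to within 1e-9 relative.
#'
#' @param mesh a [triangle_mesh].
#' @inheritParams read_mesh
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = NULL) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  format <- match.arg(tolower(format), c("obj", "ply"))
  v <- mesh$vertices
  f <- mesh$faces
  if (format == "obj") {
    out <- c("# windcanopy mesh",
             sprintf("v %.17g %.17g %.17g", v[, 1L], v[, 2L], v[, 3L]),
             sprintf("f %d %d %d", f[, 1L], f[, 2L], f[, 3L]))
  } else {
    out <- c("ply", "format ascii 1.0",
             sprintf("element vertex %d", nrow(v)),
             "property double x", "property double y", "property double z",
             sprintf("element face %d", nrow(f)),
             "property list uchar int vertex_indices", "end_header",
             sprintf("%.17g %.17g %.17g", v[, 1L], v[, 2L], v[, 3L]),
             sprintf("3 %d %d %d", f[, 1L] - 1L, f[, 2L] - 1L, f[, 3L] - 1L))
  }
  writeLines(out, path)
  invisible(path)
}

# Rigid-transform helpers ------------------------------------------------

# Rotation matrix about unit axis k by angle (radians), Rodrigues form.
rotation_matrix <- function(axis, angle) {
  k <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, k[3L], -k[2L], -k[3L], 0, k[1L], k[2L], -k[1L], 0), 3L, 3L)
  diag(3L) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# Apply `vertices %*% t(R)` about a pivot point, preserving faces/leaf ids.
transform_mesh <- function(mesh, R = diag(3), translate = c(0, 0, 0),
                           pivot = c(0, 0, 0)) {
  v <- sweep(mesh$vertices, 2L, pivot)
  v <- v %*% t(R)
  v <- sweep(v, 2L, pivot + translate, `+`)
  triangle_mesh(v, mesh$faces, leaf_id = mesh$leaf_id)
}
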