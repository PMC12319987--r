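#' Triangulated hemisphere surface
#'
#' Constructs a `surface_mesh`: a triangulated cortical hemisphere surface
#' with per-vertex areas derived from the face geometry. Coordinates are in
#' millimetres; areas in mm^2. Faces use 1-based vertex indices (format
#' readers translate from the 0-based on-disk conventions).
#'
#' Each vertex receives one third of the area of every incident triangle
#' (barycentric split), so the vertex areas sum exactly to the total face
#' area. Degenerate (zero-area) faces are permitted and contribute nothing.
#'
#' @param vertices numeric matrix, n x 3, vertex coordinates in mm.
#' @param faces integer matrix, m x 3, 1-based vertex indices per triangle.
#' @param hemisphere `"left"` or `"right"`.
#' @return An object of class `surface_mesh` with components `vertices`,
#'   `faces`, `hemisphere` and `vertex_area` (numeric vector, mm^2).
#' @examples
#' tri <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
#'                     rbind(c(1, 2, 3)))
#' sum(tri$vertex_area)  # 0.5
#' @export
surface_mesh <- function(vertices, faces, hemisphere = c("left", "right")) {
  hemisphere <- match.arg(hemisphere)
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (nrow(vertices) == 0L) stop("mesh has zero vertices")
  if (ncol(vertices) != 3L) stop("'vertices' must be an n x 3 matrix")
  if (ncol(faces) != 3L) stop("'faces' must be an m x 3 matrix")
  if (nrow(faces) > 0L && (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face index out of range (valid: 1..", nrow(vertices), ")")
  mesh <- structure(
    list(hemisphere = hemisphere, vertices = vertices, faces = faces,
         vertex_area = NULL),
    class = "surface_mesh")
  mesh$vertex_area <- compute_vertex_areas(mesh)
  mesh
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %s hemisphere, %d vertices, %d faces, area %.2f mm^2\n",
              x$hemisphere, nrow(x$vertices), nrow(x$faces),
              sum(x$vertex_area)))
  invisible(x)
}

#' Triangle areas of a mesh
#'
#' @param mesh a `surface_mesh` (or a list with `vertices` and `faces`).
#' @return numeric vector of per-face areas (mm^2), all `>= 0`.
#' @export
face_areas <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  if (nrow(f) == 0L) return(numeric(0))
  a <- v[f[, 2L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  b <- v[f[, 3L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  cx <- a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L]
  cy <- a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L]
  cz <- a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Barycentric per-vertex areas
#'
#' Assigns each vertex one third of the area of every triangle incident to
#' it. The assignment is conservative: `sum(compute_vertex_areas(m))`
#' equals `sum(face_areas(m))` up to floating-point rounding.
#'
#' @inheritParams face_areas
#' @return numeric vector of per-vertex areas (mm^2).
#' @export
compute_vertex_areas <- function(mesh) {
  fa <- face_areas(mesh)
  va <- numeric(nrow(mesh$vertices))
  if (length(fa)) {
    third <- rep(fa / 3, 3L)
    idx <- as.vector(mesh$faces)
    acc <- vapply(split(third, idx), sum, 0)
    va[as.integer(names(acc))] <- acc
  }
  va
}

#' Surface area occupied by one network
#'
#' Sums the barycentric vertex areas over the vertices a parcellation
#' assigns to `network_id`. Label 0 (medial wall / unassigned) is an
#' ordinary queryable label here; downstream statistics exclude it.
#'
#' @param mesh a `surface_mesh`.
#' @param parc a [parcellation()] for the same hemisphere and vertex count.
#' @param network_id integer network label.
#' @return area in mm^2; 0 (with a warning) if the label is absent from the
#'   parcellation's label table.
#' @export
network_surface_area <- function(mesh, parc, network_id) {
  stopifnot(inherits(mesh, "surface_mesh"), inherits(parc, "parcellation"))
  if (length(parc$labels) != nrow(mesh$vertices))
    stop("parcellation has ", length(parc$labels), " labels but mesh has ",
         nrow(mesh$vertices), " vertices")
  if (parc$hemisphere != mesh$hemisphere)
    stop("hemisphere mismatch between mesh and parcellation")
  network_id <- as.integer(network_id)
  if (network_id != 0L && !network_id %in% names_to_ids(parc$label_table))
    warning("network id ", network_id, " not in label table; area is 0")
  sum(mesh$vertex_area[parc$labels == network_id])
}

names_to_ids <- function(label_table) as.integer(names(label_table))

#' Scale a mesh
#'
#' Multiplies all coordinates by `s` and recomputes vertex areas (which
#' scale by `s^2`). Used in invariance checks.
#' @param mesh a `surface_mesh`.
#' @param s positive scale factor.
#' @export
scale_mesh <- function(mesh, s) {
  stopifnot(s > 0)
  surface_mesh(mesh$vertices * s, mesh$faces, mesh$hemisphere)
}

#' Icosphere template mesh
#'
#' Builds a geodesic sphere by repeated midpoint subdivision of a regular
#' icosahedron, projecting new vertices back onto the sphere. Subdivision
#' level `k` gives `10 * 4^k + 2` vertices and `20 * 4^k` faces (level 3:
#' 642 / 1280; level 4: 2562 / 5120). Serves as a compact stand-in for
#' registered cortical hemisphere templates: the area bookkeeping is exact
#' regardless of vertex count.
#'
#' @param subdivisions non-negative integer subdivision level.
#' @param radius sphere radius in mm.
#' @param hemisphere `"left"` or `"right"`.
#' @return a `surface_mesh`.
#' @export
icosphere <- function(subdivisions = 3L, radius = 100,
                      hemisphere = c("left", "right")) {
  hemisphere <- match.arg(hemisphere)
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (i in seq_len(subdivisions)) {
    nf <- nrow(f)
    edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    midpoint <- new.env(parent = emptyenv())
    verts <- v
    get_mid <- function(a, b) {
      key <- edge_key(a, b)
      id <- midpoint[[key]]
      if (is.null(id)) {
        verts <<- rbind(verts, (verts[a, ] + verts[b, ]) / 2)
        id <- nrow(verts)
        midpoint[[key]] <- id
      }
      id
    }
    newf <- matrix(0L, nf * 4L, 3L)
    for (j in seq_len(nf)) {
      a <- f[j, 1L]; b <- f[j, 2L]; c_ <- f[j, 3L]
      ab <- get_mid(a, b); bc <- get_mid(b, c_); ca <- get_mid(c_, a)
      newf[(j - 1L) * 4L + 1:4, ] <- rbind(
        c(a, ab, ca), c(b, bc, ab), c(c_, ca, bc), c(ab, bc, ca))
    }
    v <- verts
    f <- newf
  }
  v <- v / sqrt(rowSums(v^2)) * radius
  surface_mesh(v, f, hemisphere)
}

#' Vertex adjacency list of a mesh
#'
#' @param mesh a `surface_mesh`.
#' @return list of integer vectors; element `i` holds the neighbours of
#'   vertex `i` (sorted, unique).
#' @export
mesh_adjacency <- function(mesh) {
  f <- mesh$faces
  from <- c(f[, 1L], f[, 2L], f[, 3L], f[, 2L], f[, 3L], f[, 1L])
  to   <- c(f[, 2L], f[, 3L], f[, 1L], f[, 1L], f[, 2L], f[, 3L])
  adj <- split(to, factor(from, levels = seq_len(nrow(mesh$vertices))))
  lapply(adj, function(x) sort(unique(x)))
}
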